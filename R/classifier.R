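#' Build the marker panel of the NSN-SN chromatin-stage classifier
#'
#' Intersects significant transcripts (padj < `padj_threshold`) from a
#' differential-expression table with an external reference DEG id list,
#' splits them by direction and takes the top `n_down` down-regulated and
#' `n_up` up-regulated transcripts by ascending adjusted p-value (ties by
#' |LFC| descending, then transcript id). The 65 + 35 default reproduces
#' the 100-transcript classifier construction. Ranking is recomputed
#' internally, so the result is invariant to the row order of `de`.
#'
#' @param de DE table from [differential_expression()] (needs
#'   `transcript_id`, `lfc`, `padj`).
#' @param reference_deg_ids Character vector of externally reported DEG
#'   ids; overlap is by identity, direction agreement is not required.
#' @param n_down,n_up Panel sizes per direction (defaults 65 and 35).
#' @param padj_threshold Significance cut-off (default 0.05).
#' @return An unfitted classifier of class `nsn_sn_classifier`; complete
#'   it with [fit_reference()].
#' @export
build_classifier <- function(de, reference_deg_ids, n_down = 65, n_up = 35,
                             padj_threshold = 0.05) {
  stopifnot(all(c("transcript_id", "lfc", "padj") %in% names(de)))
  cand <- de %>%
    filter(!is.na(.data$padj), .data$padj < padj_threshold,
           .data$transcript_id %in% reference_deg_ids) %>%
    arrange(.data$padj, desc(abs(.data$lfc)), .data$transcript_id)
  down <- filter(cand, .data$lfc < 0)
  up <- filter(cand, .data$lfc > 0)
  if (nrow(down) < n_down || nrow(up) < n_up) {
    abort(sprintf(paste0(
      "insufficient marker candidates: %d down-regulated available ",
      "(need %d), %d up-regulated available (need %d)"),
      nrow(down), n_down, nrow(up), n_up))
  }
  markers <- bind_rows(
    mutate(head(down, n_down), direction = "down_in_SN"),
    mutate(head(up, n_up), direction = "up_in_SN")
  ) %>%
    select("transcript_id", "direction", "padj", "lfc")
  structure(
    list(markers = markers, n_down = n_down, n_up = n_up,
         padj_threshold = padj_threshold, fitted = FALSE),
    class = "nsn_sn_classifier"
  )
}

#' Fit the classifier's reference projection and centroids
#'
#' Normalizes the reference counts (median-of-ratios), subsets to the
#' marker panel, Z-scores each marker's log2 normalized expression across
#' the reference samples (storing the mean and sd for later queries),
#' fits a PCA on the Z-matrix and records the NSN and SN centroids in the
#' top-`k` principal-component space.
#'
#' @param model Classifier from [build_classifier()].
#' @param counts Reference wide count tibble containing every marker.
#' @param meta Reference metadata; at least 3 NSN and 3 SN samples.
#' @param k Number of principal components retained (default 2).
#' @return The fitted `nsn_sn_classifier`.
#' @export
fit_reference <- function(model, counts, meta, k = 2) {
  stopifnot(inherits(model, "nsn_sn_classifier"))
  m <- counts_to_matrix(counts)
  meta <- check_meta(meta, colnames(m))
  if (sum(meta$stage == "NSN") < 3 || sum(meta$stage == "SN") < 3) {
    abort("reference needs >= 3 NSN and >= 3 SN samples")
  }
  absent <- setdiff(model$markers$transcript_id, rownames(m))
  if (length(absent) > 0) {
    abort(sprintf("markers absent from reference: %s",
                  paste(head(absent, 10), collapse = ", ")))
  }
  sf <- size_factors(m)
  lognorm <- log2(sweep(m, 2, sf, "/") + 1)
  z_in <- lognorm[model$markers$transcript_id, , drop = FALSE]
  mu <- rowMeans(z_in)
  sdv <- apply(z_in, 1, sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    warn(sprintf("dropping %d zero-variance marker(s); panel size now %d",
                 sum(zero_var), sum(!zero_var)))
    model$markers <- model$markers[!zero_var, , drop = FALSE]
    z_in <- z_in[!zero_var, , drop = FALSE]
    mu <- mu[!zero_var]; sdv <- sdv[!zero_var]
  }
  z <- t((z_in - mu) / sdv)      # samples x markers
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pca$rotation))
  rotation <- pca$rotation[, seq_len(k), drop = FALSE]
  scores <- z %*% rotation
  ref_stage <- meta$stage
  centroids <- rbind(
    NSN = colMeans(scores[ref_stage == "NSN", , drop = FALSE]),
    SN = colMeans(scores[ref_stage == "SN", , drop = FALSE])
  )
  model$marker_mean <- mu
  model$marker_sd <- sdv
  model$rotation <- rotation
  model$centroids <- centroids
  model$k <- k
  model$ref_scores <- scores
  model$ref_meta <- meta
  model$fitted <- TRUE
  model
}

#' Classify query samples as NSN, SN or unclassified
#'
#' Query counts are normalized with their own median-of-ratios size
#' factors, subset to the marker panel, scaled with the stored reference
#' mean/sd and projected with the stored loadings; no refitting against
#' the query. A sample is called for the nearer centroid when the
#' distance ratio `d_near / d_far` is at most `ratio_threshold`
#' (the "clear clustering" rule); otherwise it is `unclassified`. Markers
#' missing from the query (at most 20%) are imputed at the reference mean.
#'
#' @param model Fitted classifier.
#' @param counts Query wide count tibble.
#' @param meta Optional query metadata, joined onto the result.
#' @param ratio_threshold Clear-clustering threshold (default 0.8).
#' @return Tibble of stage calls: `sample_id`, `call`, `dist_nsn`,
#'   `dist_sn`, `confidence_ratio`, and the projected coordinates
#'   `PC1`..`PCk`.
#' @export
classify_stage <- function(model, counts, meta = NULL, ratio_threshold = 0.8) {
  stopifnot(inherits(model, "nsn_sn_classifier"), isTRUE(model$fitted))
  m <- counts_to_matrix(counts)
  ids <- model$markers$transcript_id
  present <- ids %in% rownames(m)
  if (mean(present) < 0.8) {
    abort(sprintf("only %.0f%% of markers present in query (>= 80%% required)",
                  100 * mean(present)))
  }
  if (any(!present)) {
    inform(sprintf("imputing %d missing marker(s) at the reference mean",
                   sum(!present)))
  }
  sf <- size_factors(m)
  lognorm <- log2(sweep(m, 2, sf, "/") + 1)
  z <- matrix(0, nrow = length(ids), ncol = ncol(m),
              dimnames = list(ids, colnames(m)))
  z[present, ] <- (lognorm[ids[present], , drop = FALSE] -
                     model$marker_mean[present]) / model$marker_sd[present]
  scores <- t(z) %*% model$rotation
  d_nsn <- sqrt(rowSums((scores - matrix(model$centroids["NSN", ],
                                         nrow(scores), model$k, byrow = TRUE))^2))
  d_sn <- sqrt(rowSums((scores - matrix(model$centroids["SN", ],
                                        nrow(scores), model$k, byrow = TRUE))^2))
  d_near <- pmin(d_nsn, d_sn)
  d_far <- pmax(d_nsn, d_sn)
  ratio <- ifelse(d_far == 0, 1, d_near / d_far)
  call <- ifelse(ratio <= ratio_threshold,
                 ifelse(d_nsn < d_sn, "NSN", "SN"), "unclassified")
  out <- bind_cols(
    tibble(sample_id = colnames(m), call = unname(call),
           dist_nsn = unname(d_nsn), dist_sn = unname(d_sn),
           confidence_ratio = unname(ratio)),
    as_tibble(scores)
  )
  if (!is.null(meta)) out <- left_join(out, meta, by = "sample_id")
  out
}

#' Compare NSN/SN proportions between two conditions
#'
#' Per-condition NSN / SN / unclassified proportions plus a two-sided
#' Fisher exact test on the 2x2 table of classified calls.
#'
#' @param calls Stage-call tibble from [classify_stage()] with an added
#'   `condition` column (exactly two conditions).
#' @return List with `proportions` (tibble) and `test` (one-row tibble
#'   with `odds_ratio` and `p_value`).
#' @export
cohort_skew_report <- function(calls) {
  stopifnot(all(c("call", "condition") %in% names(calls)))
  conds <- unique(calls$condition)
  if (length(conds) != 2) abort("exactly two conditions are required")
  classified <- filter(calls, .data$call %in% c("NSN", "SN"))
  if (any(!conds %in% classified$condition)) {
    abort("each condition needs at least one classified sample")
  }
  props <- calls %>%
    count(.data$condition, .data$call) %>%
    group_by(.data$condition) %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
  tab <- table(factor(classified$condition, levels = conds),
               factor(classified$call, levels = c("NSN", "SN")))
  ft <- fisher.test(tab)
  list(proportions = props,
       test = tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value))
}

#' @export
print.nsn_sn_classifier <- function(x, ...) {
  cat(sprintf("<nsn_sn_classifier> %d markers (%d down, %d up in SN); %s\n",
              nrow(x$markers), sum(x$markers$direction == "down_in_SN"),
              sum(x$markers$direction == "up_in_SN"),
              if (isTRUE(x$fitted)) "fitted" else "unfitted"))
  invisible(x)
}
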