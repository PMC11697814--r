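#' Count detected transcripts per sample
#'
#' A transcript counts as detected in a sample when its raw count is at
#' least `min_count` (default 1).
#'
#' @param counts Wide count tibble: `transcript_id` plus one column per
#'   sample.
#' @param meta Optional sample metadata tibble (`sample_id`, `stage`, and
#'   typically `total_reads`); joined onto the result when provided.
#' @param min_count Detection threshold on the raw count.
#' @return Tibble with `sample_id`, `detected`, plus metadata columns.
#' @export
detected_transcripts <- function(counts, meta = NULL, min_count = 1) {
  m <- counts_to_matrix(counts)
  if (nrow(m) == 0) abort("count matrix is empty")
  out <- tibble(sample_id = colnames(m),
                detected = as.integer(colSums(m >= min_count)))
  if (!is.null(meta)) out <- left_join(out, meta, by = "sample_id")
  out
}

#' Depth-matched comparison of detected-transcript counts
#'
#' Two-sided Wilcoxon rank-sum test comparing NSN vs SN detected-transcript
#' counts, restricted to samples whose total reads fall inside `band`.
#' The test is exact when both groups have at most 25 samples and no ties,
#' otherwise the normal approximation with continuity correction is used.
#'
#' @param detected Tibble from [detected_transcripts()] carrying `stage`
#'   and `total_reads`.
#' @param band Length-2 numeric `(min_reads, max_reads)`, inclusive.
#' @return One-row tibble: `statistic`, `p_value`, `n_nsn`, `n_sn`,
#'   `method`.
#' @export
depth_matched_comparison <- function(detected, band) {
  stopifnot(all(c("stage", "total_reads", "detected") %in% names(detected)))
  inside <- detected$total_reads >= band[1] & detected$total_reads <= band[2]
  d <- detected[inside & detected$stage %in% c("NSN", "SN"), ]
  x <- d$detected[d$stage == "NSN"]
  y <- d$detected[d$stage == "SN"]
  if (length(x) == 0 || length(y) == 0) {
    abort(sprintf("depth band [%g, %g] leaves an empty group (NSN n=%d, SN n=%d)",
                  band[1], band[2], length(x), length(y)))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 25 && length(y) <= 25 && !has_ties
  wt <- wilcox.test(x, y, exact = use_exact, correct = TRUE)
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_nsn = length(x), n_sn = length(y),
         method = if (use_exact) "exact" else "normal approximation")
}

#' Select SN-missing transcripts
#'
#' A transcript is SN-missing when it (1) has at least one count in at
#' least `ceil(nsn_min_frac * n_NSN)` NSN samples and (2) zero counts in at
#' least `ceil(sn_zero_frac * n_SN)` SN samples. The default fractions
#' generalize the 7-of-9 and 10-of-16 rule to arbitrary group sizes.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata with `sample_id` and `stage`.
#' @param nsn_min_frac,sn_zero_frac Rule fractions.
#' @return Tibble with a `transcript_id` column, in transcript order.
#' @export
sn_missing_filter <- function(counts, meta, nsn_min_frac = 7 / 9,
                              sn_zero_frac = 10 / 16) {
  m <- counts_to_matrix(counts)
  meta <- check_meta(meta, colnames(m))
  nsn <- meta$sample_id[meta$stage == "NSN"]
  sn <- meta$sample_id[meta$stage == "SN"]
  if (length(nsn) == 0 || length(sn) == 0) {
    abort("both an NSN and an SN group are required")
  }
  k_nsn <- ceiling(nsn_min_frac * length(nsn))
  k_sn <- ceiling(sn_zero_frac * length(sn))
  present_nsn <- rowSums(m[, nsn, drop = FALSE] >= 1)
  zero_sn <- rowSums(m[, sn, drop = FALSE] == 0)
  sel <- present_nsn >= k_nsn & zero_sn >= k_sn
  tibble(transcript_id = rownames(m)[sel])
}

#' Expression quartiles within a group
#'
#' Transcripts expressed in the group (at least one raw count in any group
#' sample) are ranked by their group mean normalized expression
#' (median-of-ratios size factors) and split into quartiles Q1 (lowest) to
#' Q4. Ties are broken by transcript id order; quartile sizes differ by at
#' most one. Unexpressed transcripts receive no label.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata.
#' @param group Stage label defining the group (default `"NSN"`).
#' @return Tibble: `transcript_id`, `mean_norm`, `quartile` (factor
#'   Q1-Q4).
#' @export
expression_quartiles <- function(counts, meta, group = "NSN") {
  m <- counts_to_matrix(counts)
  meta <- check_meta(meta, colnames(m))
  gcols <- meta$sample_id[meta$stage == group]
  if (length(gcols) == 0) abort(sprintf("no samples in group '%s'", group))
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  expressed <- rowSums(m[, gcols, drop = FALSE] >= 1) > 0
  mean_norm <- rowMeans(norm[, gcols, drop = FALSE])
  ids <- rownames(m)[expressed]
  mu <- mean_norm[expressed]
  ord <- order(mu, ids)
  rk <- integer(length(ids)); rk[ord] <- seq_along(ids)
  q <- ceiling(rk * 4 / length(ids))
  tibble(transcript_id = ids, mean_norm = unname(mu),
         quartile = factor(paste0("Q", q), levels = paste0("Q", 1:4)))
}

#' Chi-square test for expression-quartile bias
#'
#' Pearson chi-square of the observed quartile counts of a selected
#' transcript set against the quartile proportions of all labelled
#' (expressed) transcripts.
#'
#' @param selected Character vector (or tibble with `transcript_id`) of
#'   selected transcripts.
#' @param quartiles Quartile label tibble from [expression_quartiles()].
#' @return One-row tibble: `statistic`, `df`, `p_value`, and observed
#'   counts `Q1`-`Q4`.
#' @export
quartile_bias_test <- function(selected, quartiles) {
  if (is.data.frame(selected)) selected <- selected$transcript_id
  lab <- quartiles$quartile[match(selected, quartiles$transcript_id)]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) abort("no selected transcript carries a quartile label")
  obs <- table(lab)
  props <- as.numeric(table(quartiles$quartile)) /
    nrow(quartiles)
  if (any(props * length(lab) == 0)) {
    abort("an expected quartile count is zero; pool quartiles before testing")
  }
  ct <- suppressWarnings(chisq.test(as.numeric(obs), p = props))
  out <- tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = ct$p.value)
  bind_cols(out, as_tibble(as.list(setNames(as.integer(obs), names(obs)))))
}

#' Compare transcript over-dispersion between stages
#'
#' For each stage separately, fits a log-log trend of squared coefficient
#' of variation (CV^2) against mean normalized expression across
#' transcripts, then flags transcripts whose variance exceeds the trend via
#' a scaled-variance chi-square upper tail, BH-adjusted at `q_threshold`.
#' Transcripts with degenerate variance or zero mean in a group are
#' skipped for that group.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata; both the NSN and SN group need at least 3
#'   samples.
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return Tibble with one row per transcript and group: `transcript_id`,
#'   `group`, `mean_norm`, `cv2`, `expected_cv2`, `statistic`, `p_value`,
#'   `q_value`, `overdispersed`.
#' @export
overdispersion_compare <- function(counts, meta, q_threshold = 0.05) {
  m <- counts_to_matrix(counts)
  meta <- check_meta(meta, colnames(m))
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  out <- list()
  for (g in c("NSN", "SN")) {
    gcols <- meta$sample_id[meta$stage == g]
    if (length(gcols) < 3) {
      abort(sprintf("group '%s' needs >= 3 samples", g))
    }
    x <- norm[, gcols, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    keep <- mu > 0 & v > 0
    cv2 <- v[keep] / mu[keep]^2
    fit <- stats::lm(log(cv2) ~ log(mu[keep]))
    exp_cv2 <- exp(unname(stats::fitted(fit)))
    nsamp <- length(gcols)
    stat <- (nsamp - 1) * v[keep] / (exp_cv2 * mu[keep]^2)
    p <- stats::pchisq(stat, df = nsamp - 1, lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    out[[g]] <- tibble(
      transcript_id = rownames(m)[keep], group = g,
      mean_norm = unname(mu[keep]), cv2 = unname(cv2),
      expected_cv2 = exp_cv2, statistic = unname(stat),
      p_value = unname(p), q_value = unname(q),
      overdispersed = unname(q < q_threshold)
    )
  }
  bind_rows(out)
}
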