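#' Negative-binomial Wald differential expression (SN vs NSN)
#'
#' Median-of-ratios size factors, a trended method-of-moments dispersion
#' estimate (`alpha = a0 + a1/mean`), a per-transcript negative-binomial
#' GLM with the stage covariate and size-factor offset, a Wald test on the
#' stage coefficient, BH adjustment, and an optional normal-prior
#' shrinkage of the log2 fold change. Positive LFC means higher in SN.
#' All-zero transcripts are excluded with a notice. Rows are sorted by
#' adjusted p-value with ties broken by |LFC| descending, then transcript
#' id.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata; both stages need at least 2 samples.
#' @param shrink Add a `shrunk_lfc` column (normal-prior posterior mean).
#' @return A `DE table` tibble: `transcript_id`, `base_mean`, `lfc`,
#'   `shrunk_lfc` (if requested), `se_lfc`, `p_value`, `padj`,
#'   `direction`.
#' @export
differential_expression <- function(counts, meta, shrink = TRUE) {
  m <- counts_to_matrix(counts)
  meta <- check_meta(meta, colnames(m))
  use <- meta$stage %in% c("NSN", "SN")
  m <- m[, use, drop = FALSE]
  meta <- meta[use, , drop = FALSE]
  if (sum(meta$stage == "NSN") < 2 || sum(meta$stage == "SN") < 2) {
    abort("each stage needs >= 2 samples")
  }
  nz <- rowSums(m) > 0
  if (any(!nz)) {
    inform(sprintf("excluding %d all-zero transcripts", sum(!nz)))
    m <- m[nz, , drop = FALSE]
  }
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)

  alpha <- trended_dispersion(norm, base_mean, sf)
  stage <- factor(meta$stage, levels = c("NSN", "SN"))
  off <- log(sf)

  fit_one <- function(i) {
    y <- m[i, ]
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- tryCatch(
      suppressWarnings(glm(y ~ stage + offset(off), family = fam)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_))
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2) return(c(NA_real_, NA_real_, NA_real_))
    est <- cf[2, 1]; se <- cf[2, 2]
    p <- 2 * pnorm(-abs(est / se))
    c(est, se, p)
  }
  res <- vapply(seq_len(nrow(m)), fit_one, numeric(3))
  lfc <- res[1, ] / log(2)
  se_lfc <- res[2, ] / log(2)
  p <- res[3, ]
  padj <- p.adjust(p, method = "BH")

  out <- tibble(
    transcript_id = rownames(m),
    base_mean = unname(base_mean),
    lfc = lfc, se_lfc = se_lfc,
    p_value = p, padj = padj,
    direction = sign(lfc)
  )
  if (shrink) {
    ok <- is.finite(lfc) & is.finite(se_lfc)
    tau2 <- max(mean(pmax(lfc[ok]^2 - se_lfc[ok]^2, 0)), 1e-3)
    out$shrunk_lfc <- lfc * tau2 / (tau2 + se_lfc^2)
    out <- out[, c("transcript_id", "base_mean", "lfc", "shrunk_lfc",
                   "se_lfc", "p_value", "padj", "direction")]
  }
  arrange(out, .data$padj, desc(abs(.data$lfc)), .data$transcript_id)
}

# Trended method-of-moments dispersion. Per-transcript MoM estimates are
# regressed on 1/mean; the fitted trend (floored) is used as the working
# dispersion, which is correctly specified for data whose dispersion
# follows an a0 + a1/mean law.
trended_dispersion <- function(norm, base_mean, sf) {
  v <- apply(norm, 1, var)
  xi <- mean(1 / sf)
  mom <- (v - xi * base_mean) / base_mean^2
  keep <- is.finite(mom) & mom > 0 & base_mean > 0
  if (sum(keep) >= 10) {
    fit <- stats::lm(mom[keep] ~ I(1 / base_mean[keep]))
    a0 <- max(coef(fit)[1], 1e-4)
    a1 <- max(coef(fit)[2], 0)
    alpha <- a0 + a1 / pmax(base_mean, 1e-8)
  } else {
    alpha <- rep(max(median(mom[keep]), 0.01), length(base_mean))
  }
  pmin(pmax(alpha, 1e-4), 10)
}
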