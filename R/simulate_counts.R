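#' Simulate a two-stage single-oocyte count matrix with planted truth
#'
#' Draws negative-binomial transcript counts for an NSN and an SN cohort.
#' A configured fraction of transcripts is degraded in SN cells (mean
#' multiplied by `degradation_factor`), a further low-expression subset is
#' made "SN-missing" (zeroed in at least `missing_min_frac` of SN cells),
#' and a small fraction is up-regulated. Per-transcript dispersion follows
#' a 1/mean trend (`alpha = 0.05 + 2/mean`), the standard shape of
#' single-cell RNA-seq overdispersion, so the package's NB test is
#' correctly specified on this null. Library depths vary uniformly across
#' `depth_range`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_counts` with elements `counts` (tibble,
#'   `transcript_id` plus one column per sample), `meta` (tibble with
#'   `sample_id`, `stage`, `source`, `total_reads`) and `truth` (list with
#'   per-cell stages and the degraded / missing / up-regulated transcript
#'   id sets).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 7, n_transcripts = 200))
#' dim(sim$counts)
#' @export
simulate_counts <- function(cfg) {
  validate_sim_config(cfg)
  n_t <- cfg$n_transcripts
  transcript_id <- sprintf("tx%05d", seq_len(n_t))

  # Gene-level layer: drawn under the transcriptome seed so several
  # cohorts (reference + queries) can share one transcriptome.
  gene_seed <- cfg$transcriptome_seed %||% cfg$seed
  gene <- with_seed(sub_seed(gene_seed, 11L), {
    # Relative abundances: lognormal, heavy-tailed like real transcriptomes.
    w <- rlnorm(n_t, meanlog = 0, sdlog = 1.6)
    rel <- w / sum(w)
    silenced <- runif(n_t) < cfg$frac_silenced
    up <- !silenced & runif(n_t) < cfg$frac_up
    # SN-missing transcripts come from the bottom two abundance quartiles,
    # mirroring the observation that transcripts lost in SN cells are lowly
    # expressed in NSN cells.
    low_half <- rel <= median(rel)
    eligible <- low_half & !silenced & !up
    p_miss <- if (any(eligible)) min(1, cfg$frac_missing * n_t / sum(eligible)) else 0
    missing <- eligible & runif(n_t) < p_miss
    list(rel = rel, silenced = silenced, up = up, missing = missing)
  })
  rel <- gene$rel
  silenced <- gene$silenced
  up <- gene$up
  missing <- gene$missing

  sn_factor <- rep(1, n_t)
  sn_factor[silenced] <- cfg$degradation_factor
  sn_factor[up] <- cfg$up_factor

  with_seed(sub_seed(cfg$seed, 1L), {
    n_cells <- cfg$n_nsn + cfg$n_sn
    stage <- c(rep("NSN", cfg$n_nsn), rep("SN", cfg$n_sn))
    sample_id <- c(sprintf("NSN_%02d", seq_len(cfg$n_nsn)),
                   sprintf("SN_%02d", seq_len(cfg$n_sn)))

    depth <- runif(n_cells, cfg$depth_range[1], cfg$depth_range[2])
    base_mu <- rel * mean(cfg$depth_range)
    alpha <- 0.05 + 2 / pmax(base_mu, 1e-8)
    size <- 1 / alpha

    counts <- matrix(0L, nrow = n_t, ncol = n_cells,
                     dimnames = list(transcript_id, sample_id))
    for (j in seq_len(n_cells)) {
      mu_j <- rel * depth[j]
      if (stage[j] == "SN") mu_j <- mu_j * sn_factor
      counts[, j] <- rnbinom(n_t, mu = mu_j, size = size)
    }

    # SN-missing transcripts: zeroed in a random subset of SN cells of size
    # at least ceil(missing_min_frac * n_sn), leaving detectable (low)
    # counts in the remaining SN cells.
    k_min <- ceiling(cfg$missing_min_frac * cfg$n_sn)
    sn_cols <- which(stage == "SN")
    for (i in which(missing)) {
      k <- sample(seq(k_min, cfg$n_sn), 1L)
      counts[i, sample(sn_cols, k)] <- 0L
    }

    meta <- tibble(sample_id = sample_id, stage = stage,
                   source = "synthetic", total_reads = colSums(counts))
    truth <- list(
      stage = setNames(stage, sample_id),
      degraded_ids = transcript_id[silenced],
      missing_ids = transcript_id[missing],
      up_ids = transcript_id[up],
      sn_factor = setNames(sn_factor, transcript_id)
    )
    out <- list(
      counts = bind_cols(tibble(transcript_id = transcript_id),
                         as_tibble(counts)),
      meta = meta,
      truth = truth
    )
    structure(out, class = "sim_counts")
  })
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("<sim_counts> %d transcripts x %d cells (%d NSN, %d SN)\n",
              nrow(x$counts), nrow(x$meta),
              sum(x$meta$stage == "NSN"), sum(x$meta$stage == "SN")))
  cat(sprintf("  truth: %d degraded, %d SN-missing, %d up-regulated\n",
              length(x$truth$degraded_ids), length(x$truth$missing_ids),
              length(x$truth$up_ids)))
  invisible(x)
}
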