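#' Configuration for the synthetic-data generators
#'
#' One configuration object parameterizes all three generators
#' ([simulate_counts()], [simulate_methylomes()],
#' [simulate_chip_windows()]). Defaults encode the study conditions the
#' generators emulate: a 9 NSN / 16 SN single-oocyte RNA-seq cohort with
#' library depths preserving roughly 160 reads per transcript, a bimodal
#' oocyte methylome with unmethylated / intermediate / methylated domains,
#' per-cell CpG coverage of 15% (the middle of the observed 10.1-22.0%
#' single-cell band), CpG density of 8 per kb, and seven joint histone-mark
#' window categories at their published genome-wide proportions.
#'
#' @param seed Integer master seed; every generator derives its own
#'   sub-stream from it.
#' @param transcriptome_seed Optional separate seed for the gene-level
#'   layer of [simulate_counts()] (relative abundances and the degraded /
#'   missing / up-regulated sets). Cohorts simulated with different
#'   `seed`s but the same `transcriptome_seed` share one transcriptome
#'   and differ only in their cells, so one can serve as classifier
#'   reference and the others as queries. Defaults to `seed`.
#' @param n_nsn,n_sn Number of NSN and SN cells.
#' @param n_transcripts Number of transcripts in the count matrix.
#' @param depth_range Length-2 numeric, min and max library depth (reads).
#' @param frac_silenced Fraction of transcripts degraded in SN cells (SN
#'   mean multiplied by `degradation_factor`).
#' @param degradation_factor Multiplier applied to SN means of degraded
#'   transcripts (default 0.25, a 4-fold decrease).
#' @param frac_missing Fraction of transcripts additionally made
#'   "SN-missing": drawn from the bottom two expression quartiles and set
#'   to zero in at least `missing_min_frac` of SN cells.
#' @param missing_min_frac Minimum fraction of SN cells in which an
#'   SN-missing transcript is zeroed (default 10/16).
#' @param frac_up Fraction of transcripts up-regulated in SN by `up_factor`.
#' @param up_factor Multiplier for up-regulated transcripts (default 2).
#' @param genome_spec Tibble with columns `chrom`, `length` (bp).
#' @param domain_grammar List with `props` (named proportions for the
#'   unmethylated / intermediate / methylated classes), `mean_len` and
#'   `min_len` (bp; lengths are aligned to the 2-kb quantification grid).
#' @param n_planted_dmrs Number of hyper-DMRs planted in intermediate
#'   domains.
#' @param dmr_effect Methylation difference (percentage points) added to SN
#'   cells inside planted DMRs. Zero gives a null genome.
#' @param cpg_density CpGs per kb.
#' @param coverage_frac Per-cell fraction of genome CpGs observed.
#' @param noncpg_density Non-CpG cytosine call sites per kb.
#' @param noncpg_level Named numeric, true non-CpG methylation percentage
#'   for NSN and SN cells.
#' @param n_contaminated Number of cells per cohort with somatic-like
#'   contamination (non-CpG methylation at `contaminated_noncpg_level`).
#' @param contaminated_noncpg_level Non-CpG percentage of contaminated
#'   cells (default 0.2, below the 1% contamination bound).
#' @param mark_grammar Named proportions of the seven joint-mark window
#'   categories (the remainder is the "none" class). Defaults are the
#'   published category proportions among valid 2-kb GV-oocyte windows.
#' @param window_size ChIP window width in bp (default 2000).
#' @param fraction_invalid Fraction of windows whose input RPKM is forced
#'   outside the valid band to exercise the validity filter.
#' @param enriched_rpkm_range,absent_rpkm_range Uniform ranges for mark
#'   RPKM in windows where the mark is present / absent. Degenerate ranges
#'   (min = max) force exact values.
#' @param input_valid_range Uniform range for input RPKM of valid windows.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       transcriptome_seed = NULL,
                       n_nsn = 9L,
                       n_sn = 16L,
                       n_transcripts = 5000L,
                       depth_range = c(5e5, 1.2e6),
                       frac_silenced = 0.10,
                       degradation_factor = 0.25,
                       frac_missing = 0.02,
                       missing_min_frac = 10 / 16,
                       frac_up = 0.04,
                       up_factor = 2,
                       genome_spec = default_genome_spec(),
                       domain_grammar = default_domain_grammar(),
                       n_planted_dmrs = 20L,
                       dmr_effect = 30,
                       cpg_density = 8,
                       coverage_frac = 0.15,
                       noncpg_density = 1,
                       noncpg_level = c(NSN = 4.02, SN = 4.68),
                       n_contaminated = 0L,
                       contaminated_noncpg_level = 0.2,
                       mark_grammar = default_mark_grammar(),
                       window_size = 2000L,
                       fraction_invalid = 0.05,
                       enriched_rpkm_range = c(1.5, 6),
                       absent_rpkm_range = c(0.05, 0.6),
                       input_valid_range = c(0.1, 1.5)) {
  cfg <- list(
    seed = as.integer(seed),
    transcriptome_seed = if (is.null(transcriptome_seed)) NULL else
      as.integer(transcriptome_seed),
    n_nsn = as.integer(n_nsn), n_sn = as.integer(n_sn),
    n_transcripts = as.integer(n_transcripts), depth_range = depth_range,
    frac_silenced = frac_silenced, degradation_factor = degradation_factor,
    frac_missing = frac_missing, missing_min_frac = missing_min_frac,
    frac_up = frac_up, up_factor = up_factor,
    genome_spec = as_tibble(genome_spec), domain_grammar = domain_grammar,
    n_planted_dmrs = as.integer(n_planted_dmrs), dmr_effect = dmr_effect,
    cpg_density = cpg_density, coverage_frac = coverage_frac,
    noncpg_density = noncpg_density, noncpg_level = noncpg_level,
    n_contaminated = as.integer(n_contaminated),
    contaminated_noncpg_level = contaminated_noncpg_level,
    mark_grammar = mark_grammar, window_size = as.integer(window_size),
    fraction_invalid = fraction_invalid,
    enriched_rpkm_range = enriched_rpkm_range,
    absent_rpkm_range = absent_rpkm_range,
    input_valid_range = input_valid_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_genome_spec <- function() {
  tibble(chrom = c("chr1", "chr2", "chr3", "chr4"),
         length = rep(24e6, 4))
}

#' @rdname sim_config
#' @export
default_domain_grammar <- function() {
  # Gamma-distributed domain lengths (shape 4) with a 36-kb floor: the
  # synthetic benchmark operates in the deep-pooled-coverage regime the
  # pseudobulk consensus procedure is designed for (several hundred CpG
  # observations per domain and group at 15% per-cell coverage).
  list(
    props    = c(unmethylated = 0.30, intermediate = 0.45, methylated = 0.25),
    mean_len = c(unmethylated = 64000, intermediate = 48000, methylated = 56000),
    min_len  = 36000,
    shape    = 4
  )
}

#' @rdname sim_config
#' @export
default_mark_grammar <- function() {
  # Published proportions of the seven joint-mark classes among the
  # 1,186,323 valid 2-kb GV-oocyte windows; remainder is "none".
  n_valid <- 1186323
  c("H3K4me3+H3K27me3"          = 106063 / n_valid,
    "H3K4me3"                   = 169128 / n_valid,
    "H3K27me3"                  = 218973 / n_valid,
    "H3K36me3+H3K4me3+H3K27me3" = 6132   / n_valid,
    "H3K36me3+H3K4me3"          = 54094  / n_valid,
    "H3K36me3+H3K27me3"         = 24404  / n_valid,
    "H3K36me3"                  = 292361 / n_valid)
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_silenced", "frac_missing", "missing_min_frac",
                   "frac_up", "coverage_frac", "fraction_invalid")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_cfg(f, "must be a fraction in [0, 1]")
    }
  }
  if (cfg$n_nsn < 1 || cfg$n_sn < 1) stop_cfg("n_nsn/n_sn", "must be >= 1")
  if (cfg$n_transcripts < 1) stop_cfg("n_transcripts", "must be >= 1")
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] > cfg$depth_range[2] ||
      cfg$depth_range[1] <= 0) {
    stop_cfg("depth_range", "must be (min, max) with 0 < min <= max")
  }
  if (!all(c("chrom", "length") %in% names(cfg$genome_spec)) ||
      nrow(cfg$genome_spec) == 0) {
    stop_cfg("genome_spec", "must be a nonempty tibble with chrom and length")
  }
  dg <- cfg$domain_grammar
  if (!all(c("props", "mean_len", "min_len") %in% names(dg)) ||
      abs(sum(dg$props) - 1) > 1e-8 || any(dg$props < 0)) {
    stop_cfg("domain_grammar", "props must be non-negative and sum to 1")
  }
  if (cfg$dmr_effect < 0) stop_cfg("dmr_effect", "must be >= 0")
  if (cfg$cpg_density <= 0) stop_cfg("cpg_density", "must be > 0")
  if (sum(cfg$mark_grammar) > 1 + 1e-8 || any(cfg$mark_grammar < 0)) {
    stop_cfg("mark_grammar", "category proportions must be >= 0 and sum to <= 1")
  }
  if (cfg$window_size < 2) stop_cfg("window_size", "must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cells: %d NSN + %d SN, %d transcripts\n",
              x$n_nsn, x$n_sn, x$n_transcripts))
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb, %g CpG/kb\n",
              nrow(x$genome_spec), sum(x$genome_spec$length) / 1e6,
              x$cpg_density))
  cat(sprintf("  planted DMRs: %d at %+g points; CpG coverage %.0f%%\n",
              x$n_planted_dmrs, x$dmr_effect, 100 * x$coverage_frac))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
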