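#' QC-filter single-cell bisulfite call sets
#'
#' Cells are retained when mapping efficiency exceeds `min_mapping`
#' percent, the number of distinct CpGs covered exceeds `min_cpgs`, and
#' the global non-CpG methylation level is not below the contamination
#' bound (`noncpg_bounds[1]`; a near-zero non-CpG level combined with high
#' CpG methylation indicates somatic-cell contamination). Both paper-style
#' thresholds are strict: a cell at exactly the threshold fails.
#'
#' @param cells Cell tibble ([simulate_methylomes()] layout: `cell_id`,
#'   `stage`, `mapping_efficiency`, `n_cpg`, `calls` list-column).
#' @param min_mapping Minimum mapping efficiency, percent (default 10).
#' @param min_cpgs Minimum distinct CpGs covered (default 500000).
#' @param noncpg_bounds Length-2 numeric; cells with global non-CpG
#'   methylation below the first bound are flagged as contaminated
#'   (default `c(1, 100)`).
#' @return List with `cells` (passing rows) and `report` (per-cell tibble
#'   of metrics and verdicts).
#' @export
qc_filter <- function(cells, min_mapping = 10, min_cpgs = 500000,
                      noncpg_bounds = c(1, 100)) {
  stopifnot(all(c("cell_id", "mapping_efficiency", "n_cpg", "calls") %in%
                  names(cells)))
  noncpg_pct <- map_dbl(cells$calls, function(cc) {
    nc <- cc[cc$context != "CpG", ]
    if (nrow(nc) == 0) return(NA_real_)
    100 * sum(nc$meth) / sum(nc$meth + nc$unmeth)
  })
  report <- tibble(
    cell_id = cells$cell_id,
    mapping_efficiency = cells$mapping_efficiency,
    pass_mapping = cells$mapping_efficiency > min_mapping,
    n_cpg = cells$n_cpg,
    pass_cpgs = cells$n_cpg > min_cpgs,
    noncpg_pct = noncpg_pct,
    contaminated = !is.na(noncpg_pct) & noncpg_pct < noncpg_bounds[1],
    pass = NA
  )
  report$pass <- report$pass_mapping & report$pass_cpgs & !report$contaminated
  if (!any(report$pass)) warn("no cell passes QC")
  list(cells = cells[report$pass, , drop = FALSE], report = report)
}

#' Global methylation percentage
#'
#' `100 * sum(meth) / sum(meth + unmeth)` over calls in the requested
#' context. Accepts either a single calls tibble or a cells tibble with a
#' `calls` list-column (returning one row per cell). Cells without calls
#' in the context are reported as `NA`.
#'
#' @param x Calls tibble or cells tibble.
#' @param context `"CpG"` (default) or `"non-CpG"`.
#' @return A single-row tibble (`global_pct`, `n_calls`) or a per-cell
#'   tibble (`cell_id`, `global_pct`, `n_calls`).
#' @export
global_methylation <- function(x, context = "CpG") {
  one <- function(cc) {
    cc <- cc[cc$context == context, ]
    n <- nrow(cc)
    if (n == 0) return(c(NA_real_, 0))
    c(100 * sum(cc$meth) / sum(cc$meth + cc$unmeth), n)
  }
  if ("calls" %in% names(x) && is.list(x$calls)) {
    vals <- vapply(x$calls, one, numeric(2))
    tibble(cell_id = x$cell_id, global_pct = vals[1, ],
           n_calls = as.integer(vals[2, ]))
  } else {
    v <- one(x)
    tibble(global_pct = v[1], n_calls = as.integer(v[2]))
  }
}

#' Segment a methylation track into domains
#'
#' Contiguous runs of windows with methylation below `low` become
#' unmethylated domains, runs above `high` methylated domains, and the
#' remaining covered territory intermediate domains. Adjacent same-class
#' windows are merged (runs split at chromosome changes and coverage
#' gaps); the classes partition the covered genome.
#'
#' @param track Tibble of genome-ordered windows: `chrom`, `start`, `end`,
#'   `meth` (percent). Windows with `NA` methylation are treated as
#'   uncovered.
#' @param low,high Class bounds in percent (defaults 25 and 70).
#' @return Domain tibble: `chrom`, `start`, `end`, `class`, `domain_id`.
#' @export
segment_domains <- function(track, low = 25, high = 70) {
  if (low >= high) stop_cfg("low/high", "requires low < high")
  stopifnot(all(c("chrom", "start", "end", "meth") %in% names(track)))
  t <- track[!is.na(track$meth), ]
  t <- t[order(t$chrom, t$start), ]
  if (nrow(t) == 0) return(tibble(chrom = character(), start = numeric(),
                                  end = numeric(), class = character(),
                                  domain_id = character()))
  cls <- ifelse(t$meth < low, "unmethylated",
                ifelse(t$meth > high, "methylated", "intermediate"))
  new_run <- c(TRUE, cls[-1] != cls[-nrow(t)] |
                 t$chrom[-1] != t$chrom[-nrow(t)] |
                 t$start[-1] != t$end[-nrow(t)])
  run <- cumsum(new_run)
  out <- tibble(chrom = t$chrom, start = t$start, end = t$end,
                class = cls, run = run) %>%
    group_by(.data$run) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), class = first(.data$class),
              .groups = "drop") %>%
    select(-"run") %>%
    arrange(.data$chrom, .data$start)
  out$domain_id <- sprintf("dom%05d", seq_len(nrow(out)))
  out
}

#' Feature enrichment of an interval set against a universe
#'
#' Compares the fraction of query intervals overlapping a feature set with
#' the overlap fraction of size-matched random draws from the universe
#' (sampling `nrow(query)` universe intervals without replacement,
#' `n_random` seeded draws). Reports the Fisher odds ratio and p-value of
#' the 2x2 table (query vs the first random draw, overlapping vs not) and
#' `log2(observed fraction / mean random fraction)`. Zero margins receive
#' the Haldane-Anscombe 0.5 correction.
#'
#' @param query,feature,universe Interval tibbles (`chrom`, `start`,
#'   `end`); the universe must contain at least as many intervals as the
#'   query.
#' @param n_random Number of random draws (default 1000).
#' @param seed Seed for the random draws.
#' @return One-row tibble: `n_query`, `n_overlap`, `frac_query`,
#'   `mean_random_frac`, `odds_ratio`, `log2_fe`, `p_value`.
#' @export
feature_enrichment <- function(query, feature, universe, n_random = 1000,
                               seed = 1) {
  if (nrow(universe) < nrow(query)) {
    abort("universe must contain at least as many intervals as the query")
  }
  n_q <- nrow(query)
  obs <- sum(count_overlaps_tbl(query, feature) > 0)
  uni_hits <- count_overlaps_tbl(universe, feature) > 0
  rand_counts <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      sum(uni_hits[sample.int(nrow(universe), n_q)])
    }, numeric(1))
  })
  mean_rand <- mean(rand_counts)
  tab <- matrix(c(obs, n_q - obs, rand_counts[1], n_q - rand_counts[1]),
                nrow = 2, byrow = TRUE)
  if (any(tab == 0)) {
    inform("zero margin in enrichment table; Haldane-Anscombe 0.5 applied")
    or <- (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    p <- fisher.test(tab)$p.value
  } else {
    ft <- fisher.test(tab)
    or <- unname(ft$estimate)
    p <- ft$p.value
  }
  frac_q <- obs / n_q
  frac_r <- mean_rand / n_q
  log2_fe <- log2((obs + ifelse(obs == 0 | mean_rand == 0, 0.5, 0)) /
                    (mean_rand + ifelse(obs == 0 | mean_rand == 0, 0.5, 0)))
  tibble(n_query = n_q, n_overlap = obs, frac_query = frac_q,
         mean_random_frac = frac_r, odds_ratio = or,
         log2_fe = log2_fe, p_value = p)
}
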