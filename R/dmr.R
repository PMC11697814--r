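# Pseudobulk consensus DMR calling.

#' Draw random pseudobulk groups per stage
#'
#' For each stage, samples `n_groups` disjoint groups of `group_size`
#' cells without replacement. Deterministic given the seed.
#'
#' @param cells Cell tibble with `cell_id` and `stage`.
#' @param group_size Cells per group (default 4).
#' @param n_groups Groups per stage (default 3).
#' @param seed RNG seed.
#' @return Tibble: `cell_id`, `stage`, `group`.
#' @export
pseudobulk_groups <- function(cells, group_size = 4, n_groups = 3, seed = 1) {
  need <- group_size * n_groups
  with_seed(seed, {
    out <- lapply(unique(cells$stage), function(st) {
      ids <- cells$cell_id[cells$stage == st]
      if (length(ids) < need) {
        abort(sprintf(
          "stage '%s' has %d cells; %d required (%d groups of %d)",
          st, length(ids), need, n_groups, group_size))
      }
      chosen <- sample(ids, need)
      tibble(cell_id = chosen, stage = st,
             group = rep(seq_len(n_groups), each = group_size))
    })
    bind_rows(out)
  })
}

# Aggregate every cell's CpG calls into per-domain (meth, total) counts.
# Returns a list of two cells x domains matrices. Computed once and reused
# across iterations.
aggregate_domain_counts <- function(cells, domains) {
  n_c <- nrow(cells)
  n_d <- nrow(domains)
  meth <- matrix(0, n_c, n_d, dimnames = list(cells$cell_id, domains$domain_id))
  total <- matrix(0, n_c, n_d, dimnames = dimnames(meth))
  gr_dom <- tbl_to_gr(domains)
  for (i in seq_len(n_c)) {
    cc <- cells$calls[[i]]
    cc <- cc[cc$context == "CpG", ]
    if (nrow(cc) == 0) next
    gr_pos <- GenomicRanges::GRanges(cc$chrom,
                                     IRanges::IRanges(cc$pos + 1L, cc$pos + 1L))
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(gr_pos, gr_dom, select = "first"))
    ok <- !is.na(hit)
    if (!any(ok)) next
    rs_m <- rowsum(cc$meth[ok], hit[ok])
    rs_t <- rowsum(cc$meth[ok] + cc$unmeth[ok], hit[ok])
    idx <- as.integer(rownames(rs_m))
    meth[i, idx] <- rs_m[, 1]
    total[i, idx] <- rs_t[, 1]
  }
  list(meth = meth, total = total)
}

#' Pooled methylation per domain for pseudobulk groups
#'
#' Pools member cells' CpG calls inside each domain. Percent methylation
#' is `100 * meth / total`; domains with fewer than `min_calls`
#' observations in a group are marked uncovered for that group.
#'
#' @param cells Cell tibble (with `calls` list-column).
#' @param domains Domain tibble with `domain_id`.
#' @param groups Group assignment from [pseudobulk_groups()]; when `NULL`
#'   each stage forms a single group.
#' @param min_calls Coverage threshold per domain and group (default 10).
#' @return Tibble: `domain_id`, `stage`, `group`, `meth`, `total`, `pct`,
#'   `covered`.
#' @export
domain_methylation <- function(cells, domains, groups = NULL, min_calls = 10) {
  agg <- aggregate_domain_counts(cells, domains)
  if (is.null(groups)) {
    groups <- tibble(cell_id = cells$cell_id, stage = cells$stage, group = 1L)
  }
  out <- groups %>%
    distinct(.data$stage, .data$group) %>%
    pmap(function(stage, group) {
      ids <- groups$cell_id[groups$stage == stage & groups$group == group]
      rows <- match(ids, rownames(agg$meth))
      meth <- colSums(agg$meth[rows, , drop = FALSE])
      total <- colSums(agg$total[rows, , drop = FALSE])
      tibble(domain_id = colnames(agg$meth), stage = stage, group = group,
             meth = unname(meth), total = unname(total),
             pct = ifelse(total > 0, 100 * meth / total, NA_real_),
             covered = total >= min_calls)
    }) %>%
    bind_rows()
  out
}

#' One differential-methylation iteration over pseudobulk groups
#'
#' Grouped binomial logistic regression of methylated/unmethylated counts
#' on stage. With a single binary covariate the fitted stage proportions
#' are the pooled per-stage proportions, and the Wald statistic has the
#' closed form `logit(p_SN) - logit(p_NSN)` over
#' `sqrt(1/m1 + 1/u1 + 1/m2 + 1/u2)` on pooled counts; that closed form is
#' used here (it matches `glm(..., family = binomial)` exactly). A domain
#' is called when the two-sided p-value is below `alpha` AND the pooled
#' difference exceeds `diff_threshold` percentage points (strictly). When
#' a pooled count is zero (perfect separation) the Fisher exact test on
#' the pooled 2x2 table is used instead.
#'
#' Only domains covered (per `covered`) in every group are testable.
#'
#' @param dom_meth Group-level tibble from [domain_methylation()] covering
#'   both stages.
#' @param diff_threshold Minimum pooled difference, percentage points
#'   (default 10; strict inequality).
#' @param alpha Per-iteration significance level (default 0.05).
#' @return Per-domain tibble: `domain_id`, `pct_nsn`, `pct_sn`, `diff`
#'   (SN minus NSN), `p_value`, `testable`, `called`, `sign`.
#' @export
dmr_iteration <- function(dom_meth, diff_threshold = 10, alpha = 0.05) {
  n_groups_total <- nrow(distinct(dom_meth, .data$stage, .data$group))
  agg <- dom_meth %>%
    group_by(.data$domain_id) %>%
    summarise(
      m1 = sum(.data$meth[.data$stage == "NSN"]),
      t1 = sum(.data$total[.data$stage == "NSN"]),
      m2 = sum(.data$meth[.data$stage == "SN"]),
      t2 = sum(.data$total[.data$stage == "SN"]),
      testable = sum(.data$covered) == n_groups_total,
      .groups = "drop"
    )
  pooled_wald_test(agg$domain_id, agg$m1, agg$t1, agg$m2, agg$t2,
                   agg$testable, diff_threshold, alpha)
}

# Closed-form grouped-logistic Wald test on pooled per-stage counts,
# shared by dmr_iteration() and the vectorized call_dmrs() loop.
pooled_wald_test <- function(domain_id, m1, t1, m2, t2, testable,
                             diff_threshold, alpha) {
  domain_id <- unname(domain_id)
  m1 <- unname(m1); t1 <- unname(t1)
  m2 <- unname(m2); t2 <- unname(t2)
  testable <- unname(testable)
  u1 <- t1 - m1
  u2 <- t2 - m2
  p1 <- ifelse(t1 > 0, m1 / t1, NA_real_)
  p2 <- ifelse(t2 > 0, m2 / t2, NA_real_)
  diff <- 100 * (p2 - p1)

  sep <- m1 == 0 | u1 == 0 | m2 == 0 | u2 == 0
  z <- suppressWarnings(
    (log(m2 / u2) - log(m1 / u1)) / sqrt(1 / m1 + 1 / u1 + 1 / m2 + 1 / u2))
  p_val <- 2 * pnorm(-abs(z))
  if (any(sep & testable, na.rm = TRUE)) {
    for (i in which(sep & testable)) {
      p_val[i] <- fisher.test(matrix(c(m1[i], u1[i], m2[i], u2[i]),
                                     nrow = 2, byrow = TRUE))$p.value
    }
  }
  called <- testable & !is.na(p_val) & p_val < alpha &
    !is.na(diff) & abs(diff) > diff_threshold
  tibble(domain_id = domain_id,
         pct_nsn = 100 * p1, pct_sn = 100 * p2, diff = diff,
         p_value = p_val, testable = testable,
         called = called, sign = ifelse(called, sign(diff), NA_real_))
}

#' Consensus DMRs over iterations
#'
#' A domain enters the DMR table when it is called with a consistent sign
#' in at least `consensus` of the iterations in which it was testable
#' (inclusive: exactly the consensus fraction qualifies) and its mean
#' difference across testable iterations exceeds `diff_threshold` in
#' magnitude. Hyper means methylation gained in SN.
#'
#' @param iter_calls Row-bound per-iteration tibbles from
#'   [dmr_iteration()] with an `iteration` column.
#' @param consensus Consensus fraction (default 0.5).
#' @param diff_threshold Percentage-point threshold on the mean difference
#'   (default 10, strict).
#' @param domains Optional domain tibble; coordinates and class are joined
#'   when given.
#' @return DMR tibble: `domain_id`, `pct_nsn`, `pct_sn`,
#'   `mean_diff`, `consensus_frac`, `n_testable`, `class`
#'   (`hyper_in_SN` / `hypo_in_SN`), plus coordinates when available.
#' @export
consensus_dmrs <- function(iter_calls, consensus = 0.5, diff_threshold = 10,
                           domains = NULL) {
  summ <- iter_calls %>%
    filter(.data$testable) %>%
    group_by(.data$domain_id) %>%
    summarise(
      n_testable = n(),
      n_hyper = sum(.data$called & .data$sign > 0, na.rm = TRUE),
      n_hypo = sum(.data$called & .data$sign < 0, na.rm = TRUE),
      pct_nsn = mean(.data$pct_nsn),
      pct_sn = mean(.data$pct_sn),
      mean_diff = mean(.data$diff),
      .groups = "drop"
    ) %>%
    mutate(consensus_frac = pmax(.data$n_hyper, .data$n_hypo) / .data$n_testable)
  out <- summ %>%
    filter(.data$consensus_frac >= consensus,
           abs(.data$mean_diff) > diff_threshold,
           pmax(.data$n_hyper, .data$n_hypo) > 0) %>%
    mutate(class = if_else(.data$n_hyper >= .data$n_hypo,
                           "hyper_in_SN", "hypo_in_SN")) %>%
    select("domain_id", "pct_nsn", "pct_sn", "mean_diff",
           "consensus_frac", "n_testable", "class")
  if (!is.null(domains)) {
    dom_cols <- domains[, intersect(c("domain_id", "chrom", "start", "end",
                                      "class"), names(domains))]
    names(dom_cols)[names(dom_cols) == "class"] <- "domain_class"
    out <- left_join(out, dom_cols, by = "domain_id")
  }
  out
}

#' Iterative pseudobulk consensus DMR calling
#'
#' Runs the full procedure: cells' calls are aggregated per domain once;
#' each of `n_iter` iterations draws fresh pseudobulk groups (iteration
#' `i` uses the sub-seed derived from `seed` and `i`, so iterations are
#' independently reproducible), tests every domain covered in all groups
#' with the grouped logistic regression, and requires a pooled difference
#' of more than `diff_threshold` points. Domains called with consistent
#' sign in at least `consensus` of their testable iterations form the DMR
#' table.
#'
#' @param cells QC-passing cell tibble (`cell_id`, `stage`, `calls`).
#' @param domains Domain tibble.
#' @param n_iter Number of iterations (default 100).
#' @param group_size,n_groups Pseudobulk layout (defaults 4 and 3).
#' @param diff_threshold,alpha,consensus,min_calls Procedure thresholds.
#' @param seed Master seed.
#' @return Object of class `dmr_result`: list with `table` (consensus DMR
#'   tibble), `iterations` (all per-iteration calls) and `params`.
#' @export
call_dmrs <- function(cells, domains, n_iter = 100, group_size = 4,
                      n_groups = 3, diff_threshold = 10, alpha = 0.05,
                      consensus = 0.5, min_calls = 10, seed = 1) {
  agg <- aggregate_domain_counts(cells, domains)
  iter_res <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    grp <- pseudobulk_groups(cells, group_size, n_groups,
                             seed = sub_seed(seed, i))
    idx <- match(grp$cell_id, rownames(agg$meth))
    gfac <- paste(grp$stage, grp$group)
    gm <- rowsum(agg$meth[idx, , drop = FALSE], gfac)
    gt <- rowsum(agg$total[idx, , drop = FALSE], gfac)
    testable <- colSums(gt >= min_calls) == nrow(gt)
    nsn_rows <- startsWith(rownames(gm), "NSN")
    res <- pooled_wald_test(
      colnames(agg$meth),
      colSums(gm[nsn_rows, , drop = FALSE]),
      colSums(gt[nsn_rows, , drop = FALSE]),
      colSums(gm[!nsn_rows, , drop = FALSE]),
      colSums(gt[!nsn_rows, , drop = FALSE]),
      testable, diff_threshold, alpha)
    res$iteration <- i
    iter_res[[i]] <- res
  }
  iter_calls <- bind_rows(iter_res)
  tab <- consensus_dmrs(iter_calls, consensus, diff_threshold, domains)
  structure(list(table = tab, iterations = iter_calls,
                 params = list(n_iter = n_iter, group_size = group_size,
                               n_groups = n_groups,
                               diff_threshold = diff_threshold, alpha = alpha,
                               consensus = consensus, min_calls = min_calls,
                               seed = seed)),
            class = "dmr_result")
}

# Group-level counts from precomputed cell x domain matrices.
group_domain_counts <- function(agg, groups, min_calls) {
  out <- vector("list", nrow(distinct(groups, .data$stage, .data$group)))
  j <- 1L
  for (st in unique(groups$stage)) {
    for (g in unique(groups$group[groups$stage == st])) {
      ids <- groups$cell_id[groups$stage == st & groups$group == g]
      rows <- match(ids, rownames(agg$meth))
      meth <- colSums(agg$meth[rows, , drop = FALSE])
      total <- colSums(agg$total[rows, , drop = FALSE])
      out[[j]] <- tibble(domain_id = colnames(agg$meth), stage = st,
                         group = g, meth = unname(meth),
                         total = unname(total),
                         covered = unname(total >= min_calls))
      j <- j + 1L
    }
  }
  bind_rows(out)
}

#' @export
print.dmr_result <- function(x, ...) {
  n_hyper <- sum(x$table$class == "hyper_in_SN")
  cat(sprintf("<dmr_result> %d consensus DMRs (%d hyper, %d hypo in SN) over %d iterations\n",
              nrow(x$table), n_hyper, nrow(x$table) - n_hyper,
              x$params$n_iter))
  invisible(x)
}
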