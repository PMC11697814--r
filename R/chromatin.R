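# Histone-mark window quantification and joint categorization.

# Canonical category labels, in the published order.
chromatin_categories <- function() {
  c("H3K4me3+H3K27me3", "H3K4me3", "H3K27me3",
    "H3K36me3+H3K4me3+H3K27me3", "H3K36me3+H3K4me3",
    "H3K36me3+H3K27me3", "H3K36me3", "none")
}

category_label <- function(k4, k27, k36) {
  dplyr::case_when(
    k36 & k4 & k27   ~ "H3K36me3+H3K4me3+H3K27me3",
    k36 & k4         ~ "H3K36me3+H3K4me3",
    k36 & k27        ~ "H3K36me3+H3K27me3",
    k36              ~ "H3K36me3",
    k4 & k27         ~ "H3K4me3+H3K27me3",
    k4               ~ "H3K4me3",
    k27              ~ "H3K27me3",
    TRUE             ~ "none"
  )
}

#' Reads-per-kilobase-per-million for fixed windows
#'
#' `RPKM = count / (width/1000) / (library_total/1e6)`.
#'
#' @param counts Tibble with a `count` column (one row per window) or a
#'   numeric vector of window read counts.
#' @param library_total Total mapped reads in the library (> 0).
#' @param width Window width in bp (default 2000).
#' @return Input with an `rpkm` column (or a numeric vector when `counts`
#'   is a vector).
#' @export
window_rpkm <- function(counts, library_total, width = 2000) {
  if (library_total <= 0) abort("library_total must be > 0")
  f <- function(x) x / (width / 1000) / (library_total / 1e6)
  if (is.data.frame(counts)) {
    mutate(counts, rpkm = f(.data$count))
  } else {
    f(counts)
  }
}

#' Input-based window validity filter
#'
#' A window is valid when its input-control RPKM lies within
#' `[input_low, input_high]`. Exclusion is strict (`<` and `>`), so
#' windows exactly at a boundary are retained.
#'
#' @param windows Window tibble with an `input` RPKM column.
#' @param input_low,input_high Validity band (defaults 0.04 and 2).
#' @return `windows` with a logical `valid` column.
#' @export
filter_windows <- function(windows, input_low = 0.04, input_high = 2) {
  stopifnot("input" %in% names(windows))
  mutate(windows, valid = !(.data$input < input_low | .data$input > input_high))
}

#' Assign joint histone-mark categories to valid windows
#'
#' A mark is enriched in a window when its RPKM strictly exceeds
#' `enrich_threshold` (a window at exactly the threshold is not
#' enriched). The category is the exact combination of enriched marks:
#' one of the seven joint classes, or `"none"` when no mark is enriched.
#' Windows failing the validity filter get `NA`.
#'
#' @param windows Window tibble with `H3K4me3`, `H3K27me3`, `H3K36me3`
#'   RPKM columns and (optionally) a `valid` flag; when `valid` is absent
#'   all windows are treated as valid.
#' @param enrich_threshold RPKM enrichment threshold (default 1, strict).
#' @return `windows` with a `category` factor column.
#' @export
assign_categories <- function(windows, enrich_threshold = 1) {
  stopifnot(all(c("H3K4me3", "H3K27me3", "H3K36me3") %in% names(windows)))
  valid <- if ("valid" %in% names(windows)) windows$valid else TRUE
  lab <- category_label(windows$H3K4me3 > enrich_threshold,
                        windows$H3K27me3 > enrich_threshold,
                        windows$H3K36me3 > enrich_threshold)
  lab[!valid] <- NA
  mutate(windows, category = factor(lab, levels = chromatin_categories()))
}

#' Category composition across methylation-domain classes
#'
#' Assigns each categorized window to the domain containing its midpoint
#' and tabulates category counts and percentages across domain classes,
#' with a Pearson chi-square test (uncorrected) on the contingency table.
#' Categories with no windows are dropped from the test.
#'
#' @param windows Categorized window tibble (from [assign_categories()]).
#' @param domains Domain tibble with a `class` column.
#' @return List with `composition` (tibble: `category`, `class`, `n`,
#'   `pct`) and `test` (one-row tibble: `statistic`, `df`, `p_value`).
#' @export
category_by_domain <- function(windows, domains) {
  w <- windows[!is.na(windows$category), ]
  idx <- midpoint_containment(w, domains)
  keep <- !is.na(idx)
  tab <- table(droplevels(w$category[keep]), domains$class[idx[keep]])
  if (any(rowSums(tab) == 0)) {
    inform("dropping categories with zero windows from the test")
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  comp <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE)) %>%
    rlang::set_names(c("category", "class", "n")) %>%
    group_by(.data$category) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
  list(composition = comp,
       test = tibble(statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p_value = ct$p.value))
}

#' Category enrichment of windows inside a query interval set
#'
#' Tallies categorized valid windows overlapping the query intervals,
#' draws a count- and length-matched random interval set from valid-window
#' territory (`n_random` seeded draws), and reports per-category
#' `log2(query fraction / mean random fraction)` plus a chi-square test
#' comparing the query category distribution with the pooled random one.
#'
#' @param windows Categorized window tibble (with `valid` and `category`).
#' @param query Interval tibble (`chrom`, `start`, `end`).
#' @param n_random Number of random draws (default 100).
#' @param seed Seed for the random draws.
#' @return Object of class `category_enrichment`: list with
#'   `by_category` (tibble: `category`, `n_query`, `frac_query`,
#'   `mean_n_random`, `frac_random`, `log2_fe`) and `test` (chi-square
#'   tibble).
#' @export
dmr_category_enrichment <- function(windows, query, n_random = 100, seed = 1) {
  w <- windows[!is.na(windows$category), ]
  if (nrow(w) == 0) abort("no categorized windows")
  hits <- count_overlaps_tbl(w, query) > 0
  if (!any(hits)) abort("no window overlaps the query set")
  levs <- levels(droplevels(w$category))
  obs <- table(factor(w$category[hits], levels = levs))

  # Random sets: query-length intervals centred on random valid windows.
  lens <- query$end - query$start
  rand_tot <- setNames(numeric(length(levs)), levs)
  with_seed(seed, {
    for (r in seq_len(n_random)) {
      centre <- sample.int(nrow(w), nrow(query), replace = TRUE)
      mid <- floor((w$start[centre] + w$end[centre]) / 2)
      ln <- sample(lens, nrow(query), replace = length(lens) < nrow(query))
      rq <- tibble(chrom = w$chrom[centre],
                   start = pmax(0, mid - floor(ln / 2)),
                   end = mid - floor(ln / 2) + ln)
      rhit <- count_overlaps_tbl(w, rq) > 0
      rt <- table(factor(w$category[rhit], levels = levs))
      rand_tot <- rand_tot + as.numeric(rt)
    }
  })
  mean_rand <- as.numeric(rand_tot) / n_random
  obs <- as.numeric(obs)
  n_obs <- sum(obs)
  n_rand <- sum(mean_rand)
  frac_q <- obs / n_obs
  frac_r <- mean_rand / n_rand
  pad <- 0.5 * (obs == 0 | mean_rand == 0)
  log2_fe <- log2(((obs + pad) / n_obs) / ((mean_rand + pad) / n_rand))
  by_cat <- tibble(category = levs, n_query = as.integer(obs),
                   frac_query = frac_q,
                   mean_n_random = mean_rand,
                   frac_random = frac_r,
                   log2_fe = log2_fe)
  tab <- rbind(query = obs, random = round(as.numeric(rand_tot)))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(by_category = by_cat,
                 test = tibble(statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_value = ct$p.value)),
            class = "category_enrichment")
}

#' @export
print.category_enrichment <- function(x, ...) {
  cat("<category_enrichment>\n")
  print(x$by_category)
  invisible(x)
}
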