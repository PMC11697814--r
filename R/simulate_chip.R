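#' Simulate histone-mark RPKM tracks over a 2-kb window tiling
#'
#' Tiles the genome into fixed windows, assigns each a true joint-mark
#' category from `mark_grammar` (the remainder of probability mass is the
#' "none" class), and draws per-mark RPKM above the enrichment threshold
#' for marks present in the category and below it for marks absent
#' (uniformly within the configured ranges; degenerate ranges force exact
#' values). Input RPKM lies inside the validity band for most windows; a
#' `fraction_invalid` subset is forced outside it (half below, half above)
#' to exercise the validity filter.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_chip` with elements `windows` (tibble:
#'   `chrom`, `start`, `end`, `H3K4me3`, `H3K27me3`, `H3K36me3`, `input`)
#'   and `truth` (tibble with the per-window true `category` and
#'   `invalid` flag).
#' @export
simulate_chip_windows <- function(cfg) {
  validate_sim_config(cfg)
  if (nrow(cfg$genome_spec) == 0) stop_cfg("genome_spec", "must be nonempty")
  with_seed(sub_seed(cfg$seed, 3L), {
    w <- tile_genome(cfg$genome_spec, cfg$window_size)
    n <- nrow(w)
    cats <- c(names(cfg$mark_grammar), "none")
    probs <- c(cfg$mark_grammar, none = max(0, 1 - sum(cfg$mark_grammar)))
    category <- sample(cats, n, replace = TRUE, prob = probs)

    draw <- function(lo, hi, n) runif(n, lo, hi)
    rpkm_for <- function(mark) {
      present <- grepl(mark, category, fixed = TRUE)
      out <- numeric(n)
      out[present] <- draw(cfg$enriched_rpkm_range[1],
                           cfg$enriched_rpkm_range[2], sum(present))
      out[!present] <- draw(cfg$absent_rpkm_range[1],
                            cfg$absent_rpkm_range[2], sum(!present))
      out
    }
    k4 <- rpkm_for("H3K4me3")
    k27 <- rpkm_for("H3K27me3")
    k36 <- rpkm_for("H3K36me3")

    input <- draw(cfg$input_valid_range[1], cfg$input_valid_range[2], n)
    invalid <- runif(n) < cfg$fraction_invalid
    low_side <- invalid & runif(n) < 0.5
    high_side <- invalid & !low_side
    input[low_side] <- runif(sum(low_side), 0, 0.039)
    input[high_side] <- runif(sum(high_side), 2.001, 4)

    windows <- bind_cols(w, tibble(H3K4me3 = k4, H3K27me3 = k27,
                                   H3K36me3 = k36, input = input))
    truth <- bind_cols(w, tibble(category = category, invalid = invalid))
    structure(list(windows = windows, truth = truth), class = "sim_chip")
  })
}

#' Tile a genome into fixed non-overlapping windows
#'
#' @param genome_spec Tibble with `chrom` and `length` columns.
#' @param window_size Window width in bp.
#' @return Tibble of windows (`chrom`, `start`, `end`; 0-based half-open),
#'   genome-ordered. Chromosome remainders shorter than a full window are
#'   dropped.
#' @export
tile_genome <- function(genome_spec, window_size = 2000L) {
  out <- lapply(seq_len(nrow(genome_spec)), function(i) {
    n <- floor(genome_spec$length[i] / window_size)
    if (n < 1) return(NULL)
    starts <- (seq_len(n) - 1) * window_size
    tibble(chrom = genome_spec$chrom[i], start = starts,
           end = starts + window_size)
  })
  bind_rows(out)
}

#' @export
print.sim_chip <- function(x, ...) {
  cat(sprintf("<sim_chip> %d windows of %d bp; %d forced-invalid\n",
              nrow(x$windows), x$windows$end[1] - x$windows$start[1],
              sum(x$truth$invalid)))
  invisible(x)
}
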