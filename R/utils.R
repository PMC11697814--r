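# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed. Keeps the result a
# positive 32-bit integer so set.seed() accepts it.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 77777 * as.double(k)) %% 2147483587L) + 1L
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_cfg <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "oostage_config_error")
}

# Convert an interval tibble (chrom, start, end; 0-based half-open) to a
# GRanges (1-based closed), the coordinate convention IRanges uses.
tbl_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges   = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Any-overlap counts of `x` intervals against `y` intervals (both tibbles,
# BED convention). Returns an integer vector along rows of `x`.
count_overlaps_tbl <- function(x, y) {
  GenomicRanges::countOverlaps(tbl_to_gr(x), tbl_to_gr(y))
}

# Index of the `y` interval containing each midpoint of `x`; NA when the
# midpoint falls in no interval.
midpoint_containment <- function(x, y) {
  mids <- floor((x$start + x$end) / 2)
  gr_mid <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(mids + 1L, mids + 1L))
  hits <- GenomicRanges::findOverlaps(gr_mid, tbl_to_gr(y), select = "first")
  as.integer(hits)
}

# Median-of-ratios size factors (counts: transcripts x samples matrix).
# Falls back to positive-count geometric means when too few transcripts are
# expressed everywhere.
size_factors <- function(counts) {
  log_counts <- log(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(all_pos) >= 20) {
    log_geo <- rowMeans(log_counts[all_pos, , drop = FALSE])
    sf <- apply(log_counts[all_pos, , drop = FALSE], 2,
                function(x) exp(median(x - log_geo)))
  } else {
    log_counts[!is.finite(log_counts)] <- NA
    log_geo <- rowMeans(log_counts, na.rm = TRUE)
    keep <- is.finite(log_geo)
    sf <- apply(log_counts[keep, , drop = FALSE], 2, function(x) {
      exp(median(x - log_geo[keep], na.rm = TRUE))
    })
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("size factor estimation failed: a sample has no usable counts")
  }
  sf / exp(mean(log(sf)))
}

# Wide count tibble (transcript_id + one column per sample) -> integer matrix.
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "transcript_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "transcript_id"), drop = FALSE])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

check_meta <- function(meta, samples) {
  stopifnot(is.data.frame(meta), all(c("sample_id", "stage") %in% names(meta)))
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("metadata missing for samples: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  meta[match(samples, meta$sample_id), , drop = FALSE]
}
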