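# Readers and writers for the interchange formats. All genomic intervals
# are 0-based half-open (BED convention) internally; Bismark-style
# coverage positions are 1-based on disk and converted on read.

#' Read a BED3-BED6 file
#'
#' @param path File path.
#' @return Interval tibble (`chrom`, `start`, `end`, plus `name`,
#'   `score`, `strand` when present), sorted by chromosome and start.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) > 0 && (min(nf) < 3 || max(nf) > 6 || length(unique(nf)) != 1)) {
    bad <- which(nf != nf[1] | nf < 3 | nf > 6)[1]
    abort(sprintf("malformed BED line %d: expected 3-6 tab-separated fields",
                  bad))
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  out <- tibble(chrom = get(1),
                start = suppressWarnings(as.numeric(get(2))),
                end = suppressWarnings(as.numeric(get(3))))
  for (i in seq_len(nrow(out))) {
    if (!nzchar(out$chrom[i]) || is.na(out$start[i]) || is.na(out$end[i]) ||
        out$start[i] >= out$end[i]) {
      abort(sprintf("malformed BED line %d: need nonempty chrom and start < end",
                    i))
    }
  }
  if (length(fields) > 0 && nf[1] >= 4) out$name <- get(4)
  if (length(fields) > 0 && nf[1] >= 5) {
    out$score <- suppressWarnings(as.numeric(get(5)))
  }
  if (length(fields) > 0 && nf[1] >= 6) out$strand <- get(6)
  arrange(out, .data$chrom, .data$start)
}

#' Write intervals as BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent one.
  keep <- character(0)
  for (col in c("chrom", "start", "end", "name", "score", "strand")) {
    if (!col %in% cols) break
    keep <- c(keep, col)
  }
  readr::write_tsv(x[, keep], path, col_names = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage file
#'
#' Six tab-separated columns: chrom, start (1-based), end, percent
#' methylated, count methylated, count unmethylated; an optional seventh
#' column gives the cytosine context. Plain or gzipped. Positions are
#' converted to 0-based; the percent column is cross-checked against the
#' counts (tolerance 0.1 percentage points) and on conflict the counts
#' win with a warning.
#'
#' @param path File path (`.gz` accepted).
#' @param context Context assigned when the file has no context column
#'   (default `"CpG"`).
#' @return Calls tibble: `chrom`, `pos` (0-based), `context`, `meth`,
#'   `unmeth`.
#' @export
read_bismark_cov <- function(path, context = "CpG") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- suppressMessages(readr::read_tsv(path, col_names = FALSE,
                                        progress = FALSE,
                                        show_col_types = FALSE))
  if (ncol(x) < 6) abort("Bismark coverage files need >= 6 columns")
  names(x)[1:6] <- c("chrom", "start", "end", "pct", "meth", "unmeth")
  if (any(x$meth < 0 | x$unmeth < 0)) abort("negative methylation counts")
  ctx <- if (ncol(x) >= 7) as.character(x[[7]]) else context
  recomputed <- 100 * x$meth / (x$meth + x$unmeth)
  mismatch <- abs(recomputed - x$pct) > 0.1
  if (any(mismatch, na.rm = TRUE)) {
    warn(sprintf("%d record(s) with %%meth inconsistent with counts; counts win",
                 sum(mismatch, na.rm = TRUE)))
  }
  tibble(chrom = as.character(x$chrom), pos = x$start - 1,
         context = ctx, meth = as.numeric(x$meth),
         unmeth = as.numeric(x$unmeth)) %>%
    arrange(.data$chrom, .data$pos)
}

#' Write calls as a Bismark-style coverage file
#'
#' @param calls Calls tibble (`chrom`, `pos` 0-based, `context`, `meth`,
#'   `unmeth`).
#' @param path Output path.
#' @param with_context Append the context as a seventh column.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(calls, path, with_context = TRUE) {
  out <- tibble(chrom = calls$chrom, start = calls$pos + 1,
                end = calls$pos + 1,
                pct = round(100 * calls$meth / (calls$meth + calls$unmeth), 6),
                meth = calls$meth, unmeth = calls$unmeth)
  if (with_context) out$context <- calls$context
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a wide count matrix
#'
#' TSV layout: a `transcript_id` column plus one column per sample.
#' MatrixMarket layout: an `.mtx` file with sidecar `<path>.rownames` and
#' `<path>.colnames` text files.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @return Wide count tibble.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    x <- suppressMessages(readr::read_tsv(path, progress = FALSE,
                                          show_col_types = FALSE))
    stopifnot("transcript_id" %in% names(x))
    x
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    dimnames(m) <- list(rn, cn)
    bind_cols(tibble(transcript_id = rn), as_tibble(m))
  }
}

#' @rdname read_count_matrix
#' @param counts Wide count tibble.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(counts, path)
  } else {
    m <- counts_to_matrix(counts)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a bedGraph track
#'
#' Four tab-separated columns: chrom, start (0-based), end, value.
#'
#' @param path File path.
#' @param value_name Name for the value column (default `"value"`).
#' @return Tibble `chrom`, `start`, `end`, value column.
#' @export
read_bedgraph <- function(path, value_name = "value") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- suppressMessages(readr::read_tsv(path, col_names = FALSE,
                                        progress = FALSE,
                                        show_col_types = FALSE))
  if (ncol(x) != 4) abort("bedGraph files need exactly 4 columns")
  rlang::set_names(x, c("chrom", "start", "end", value_name))
}

#' @rdname read_bedgraph
#' @param track Tibble with `chrom`, `start`, `end` and one value column.
#' @export
write_bedgraph <- function(track, path, value_name = "value") {
  readr::write_tsv(track[, c("chrom", "start", "end", value_name)], path,
                   col_names = FALSE)
  invisible(path)
}
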