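# broom-style tidiers for the fitted objects.

#' Tidy an NSN-SN classifier
#'
#' @param x An `nsn_sn_classifier`.
#' @param ... Unused.
#' @return The marker panel tibble (`transcript_id`, `direction`, `padj`,
#'   `lfc`).
#' @export
tidy.nsn_sn_classifier <- function(x, ...) {
  as_tibble(x$markers)
}

#' @rdname tidy.nsn_sn_classifier
#' @return For `glance()`: a one-row tibble with panel sizes, fit state
#'   and, when fitted, the between-centroid distance and variance
#'   explained by the retained components.
#' @export
glance.nsn_sn_classifier <- function(x, ...) {
  out <- tibble(
    n_markers = nrow(x$markers),
    n_down = sum(x$markers$direction == "down_in_SN"),
    n_up = sum(x$markers$direction == "up_in_SN"),
    fitted = isTRUE(x$fitted)
  )
  if (isTRUE(x$fitted)) {
    out$k <- x$k
    out$centroid_distance <-
      sqrt(sum((x$centroids["NSN", ] - x$centroids["SN", ])^2))
  }
  out
}

#' Tidy a consensus DMR result
#'
#' @param x A `dmr_result` from [call_dmrs()].
#' @param ... Unused.
#' @return The consensus DMR tibble.
#' @export
tidy.dmr_result <- function(x, ...) {
  as_tibble(x$table)
}

#' @rdname tidy.dmr_result
#' @return For `glance()`: one-row tibble with DMR counts, the
#'   hypermethylated fraction and the iteration settings.
#' @export
glance.dmr_result <- function(x, ...) {
  n_hyper <- sum(x$table$class == "hyper_in_SN")
  tibble(
    n_dmrs = nrow(x$table),
    n_hyper = n_hyper,
    n_hypo = nrow(x$table) - n_hyper,
    pct_hyper = if (nrow(x$table) > 0) 100 * n_hyper / nrow(x$table) else NA_real_,
    n_iterations = x$params$n_iter,
    consensus = x$params$consensus,
    diff_threshold = x$params$diff_threshold
  )
}
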