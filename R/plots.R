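# ggplot2 views of the main result types.

#' Volcano plot of a differential-expression table
#'
#' Shrunken LFC (when present) against -log10 adjusted p-value, with the
#' |LFC| > 1 and padj < 0.05 cut-offs marked.
#'
#' @param de DE table from [differential_expression()].
#' @param lfc_cut,padj_cut Dashed cut-off lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_cut = 1, padj_cut = 0.05) {
  lfc_col <- if ("shrunk_lfc" %in% names(de)) "shrunk_lfc" else "lfc"
  d <- de %>%
    filter(is.finite(.data[[lfc_col]]), !is.na(.data$padj)) %>%
    mutate(
      status = dplyr::case_when(
        .data$padj < padj_cut & .data[[lfc_col]] < -lfc_cut ~ "down",
        .data$padj < padj_cut & .data[[lfc_col]] > lfc_cut ~ "up",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(.data[[lfc_col]], -log10(.data$padj),
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(padj_cut), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(down = "#2166ac", ns = "grey70",
                                            up = "#b2182b")) +
    ggplot2::labs(x = "log2 fold change (SN vs NSN)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Detected transcripts against library depth
#'
#' @param detected Tibble from [detected_transcripts()] with `stage` and
#'   `total_reads`.
#' @param band Optional depth band drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_detected <- function(detected, band = NULL) {
  p <- ggplot2::ggplot(detected,
                       ggplot2::aes(.data$total_reads, .data$detected,
                                    colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "library depth (reads)", y = "transcripts detected") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::geom_vline(xintercept = band, linetype = 2,
                                 colour = "red")
  }
  p
}

#' Stage calls in the classifier's principal-component space
#'
#' @param calls Tibble from [classify_stage()].
#' @param model Optional fitted classifier; reference samples and
#'   centroids are added when given.
#' @return A ggplot object.
#' @export
plot_stage_calls <- function(calls, model = NULL) {
  p <- ggplot2::ggplot(calls, ggplot2::aes(.data$PC1, .data$PC2,
                                           colour = .data$call)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "call") +
    ggplot2::theme_minimal()
  if (!is.null(model) && isTRUE(model$fitted)) {
    cent <- as_tibble(model$centroids, rownames = "stage")
    p <- p + ggplot2::geom_point(data = cent,
                                 ggplot2::aes(.data$PC1, .data$PC2),
                                 colour = "black", shape = 4, size = 4,
                                 inherit.aes = FALSE)
  }
  p
}

#' Methylation of domains by class and stage
#'
#' @param dom_meth Tibble from [domain_methylation()].
#' @param domains Domain tibble with `domain_id` and `class`.
#' @return A ggplot object (violin per class and stage).
#' @export
plot_domain_methylation <- function(dom_meth, domains) {
  d <- dom_meth %>%
    filter(.data$covered) %>%
    left_join(domains[, c("domain_id", "class")], by = "domain_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$pct,
                                  fill = .data$stage)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width") +
    ggplot2::labs(x = "methylation domain class", y = "CpG methylation (%)") +
    ggplot2::theme_minimal()
}

#' Per-category log2 fold enrichment
#'
#' @param enrichment A `category_enrichment` object (or its
#'   `by_category` tibble).
#' @return A ggplot object.
#' @export
plot_category_enrichment <- function(enrichment) {
  d <- if (inherits(enrichment, "category_enrichment")) {
    enrichment$by_category
  } else {
    enrichment
  }
  d$category <- factor(d$category, levels = d$category)
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$log2_fe)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "log2 fold enrichment vs random") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
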