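#' Volcano plot of a DEG table
#'
#' @param object A `ucp_deg` tibble from [call_degs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ucp_deg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p), colour = .data$call
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey60")
    ) +
    ggplot2::labs(
      x = "log2 fold change (OE / WT)", y = "-log10 p (Kal's Z-test)",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of enriched GO terms
#'
#' @param object A `ucp_enrich` tibble from [enrich()].
#' @param top Number of top terms (by adjusted p) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ucp_enrich <- function(object, top = 20, ...) {
  d <- head(dplyr::arrange(object, .data$p_adj), top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = -log10(.data$p_adj), y = stats::reorder(.data$term, -.data$p_adj),
    fill = .data$enriched
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, fill = "enriched") +
    ggplot2::theme_minimal()
}

#' Z-score plot of pathway differential expression
#'
#' @param object A `ucp_pathway_score` tibble from [pathway_z()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ucp_pathway_score <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$z, y = stats::reorder(.data$pathway_id, .data$z),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey60")
    ) +
    ggplot2::labs(x = "pathway Z-score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Metabolite volcano plot
#'
#' @param object A `ucp_volcano` tibble from [volcano_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ucp_volcano <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$p), colour = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "log2 fold change (OE / WT)", y = "-log10 p (t-test)",
      colour = "selected"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of RNA-seq vs qPCR fold changes
#'
#' @param concordance Output of [qpcr_concordance()] (its `scatter`
#'   attribute is plotted).
#' @return A ggplot object.
#' @export
plot_concordance <- function(concordance) {
  scatter <- attr(concordance, "scatter")
  if (is.null(scatter)) abort("no scatter table attached; pass qpcr_concordance() output")
  ggplot2::ggplot(scatter, ggplot2::aes(
    x = .data$rnaseq_log2fc, y = .data$qpcr_log2fc
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "RNA-seq log2 fold change", y = "qPCR log2 relative expression") +
    ggplot2::theme_minimal()
}
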