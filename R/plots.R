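#' Recurrence scatter of marker classifications
#'
#' Plots each gene's recurrence in mitochondrial vs chloroplast
#' perturbations, coloured by marker label; jitter separates the integer
#' grid.
#'
#' @param records Output of [classify_markers()].
#' @return A ggplot object.
#' @export
plot_markers <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$n_mito, y = .data$n_chloro,
                               colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.2, height = 0.2, alpha = 0.6) +
    ggplot2::labs(x = "significant in # mitochondrial perturbations",
                  y = "significant in # chloroplast perturbations",
                  colour = "marker label") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Observed/expected ratio per category with point size encoding the
#' observed overlap and colour the over-representation tail probability.
#'
#' @param results Tibble of [enrichment_test()] rows carrying a `category`
#'   column (e.g. from [category_scan()]).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ratio, y = .data$category,
                               size = .data$observed,
                               colour = .data$p_over)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#b2182b", high = "grey70") +
    ggplot2::labs(x = "observed / expected", y = NULL,
                  size = "observed", colour = "p (over)") +
    ggplot2::theme_minimal()
}

#' Heat-map style view of a response matrix
#'
#' Tiles gene-by-experiment calls (up/down/ns). Intended for the modest
#' gene sets that recur across experiments, e.g. marker genes.
#'
#' @param rm Response matrix from [response_matrix()].
#' @param genes Optional subset of genes to display.
#' @return A ggplot object.
#' @export
plot_response_matrix <- function(rm, genes = NULL) {
  if (!is.null(genes)) rm <- rm |> filter(.data$gene_id %in% genes)
  ggplot2::ggplot(rm, ggplot2::aes(x = .data$experiment, y = .data$gene_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac",
                                          ns = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
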