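#' Dot plot of marker expression by cluster
#'
#' Standard cluster-identification display: dot size is the fraction of the
#' cluster's cells expressing the gene, color is the average
#' log-normalized expression.
#'
#' @param stats A [dotplot_stats()] tibble.
#' @param gene_order Optional gene display order.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(stats, gene_order = NULL) {
  needed <- c("gene", "cluster", "avg_expression", "fraction_expressing")
  if (!all(needed %in% names(stats))) {
    abort("`stats` must come from dotplot_stats().")
  }
  if (!is.null(gene_order)) {
    stats$gene <- factor(stats$gene, levels = gene_order)
  }
  ggplot2::ggplot(stats, ggplot2::aes(
    x = .data$gene, y = .data$cluster,
    size = .data$fraction_expressing, colour = .data$avg_expression
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "grey85", high = "#2166AC") +
    ggplot2::scale_size_area(max_size = 6, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, size = "Fraction\nexpressing",
                  colour = "Average\nexpression") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
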