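#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene set network
#'
#' Nodes are gene sets (area scaled by gene count, labelled by node id);
#' edge width shows the number of shared biclusters.  Layout is
#' Kamada-Kawai, computed with a fixed RNG substream so the figure is
#' reproducible.
#'
#' @param object a `gene_set_network`.
#' @param label_nodes draw node-id labels.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gene_set_network
#' @export
autoplot.gene_set_network <- function(object, label_nodes = TRUE, ...) {
  g <- as_igraph(object)
  xy <- with_seed(1L, igraph::layout_with_kk(g))
  nd <- tibble::tibble(
    node_id = object$nodes$node_id, x = xy[, 1], y = xy[, 2],
    n_genes = object$nodes$n_genes
  )
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$node_id)]
  ed$y <- nd$y[match(ed$from, nd$node_id)]
  ed$xend <- nd$x[match(ed$to, nd$node_id)]
  ed$yend <- nd$y[match(ed$to, nd$node_id)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_genes),
      colour = "steelblue"
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2), breaks = function(lims) {
      unique(round(pretty(lims)))
    }) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "genes", linewidth = "shared\nbiclusters")
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = nd, ggplot2::aes(x = .data$x, y = .data$y, label = .data$node_id),
      vjust = -1.2, size = 3
    )
  }
  p
}

#' Plot the largest gene set network of a pipeline result
#'
#' @param object a `fimbic_result`.
#' @param ... passed to [autoplot.gene_set_network()].
#' @return a ggplot; errors if the run produced no network.
#' @method autoplot fimbic_result
#' @export
autoplot.fimbic_result <- function(object, ...) {
  if (length(object$networks) == 0) stop("result has no networks to plot", call. = FALSE)
  autoplot(object$networks[[1]], ...)
}

#' Plot bicluster sizes against significance
#'
#' One point per bicluster: cell count (log scale) versus empirical
#' p-value; a quick overview of what survived filtering and merging.
#'
#' @param biclusters scored bicluster tibble.
#' @return a ggplot.
#' @export
plot_bicluster_summary <- function(biclusters) {
  stopifnot(nrow(biclusters) > 0)
  df <- tibble::tibble(size = biclusters$size, p_value = biclusters$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$p_value)) +
    ggplot2::geom_point(alpha = 0.7, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bicluster size (cells)", y = "empirical p-value") +
    ggplot2::theme_minimal()
}
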