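#' Plot a transcriptome map (genome graph)
#'
#' Draws the classic eQTL genome graph: peak position (cumulative Mb) on the
#' x-axis against transcript position on the y-axis, one point per
#' significant probe, coloured by LRS tier (blue = low, green =
#' intermediate, red = high). The cis diagonal and vertical trans bands are
#' read directly off the plot.
#'
#' @param points Tibble from [transcriptome_map()].
#' @return A ggplot object.
#' @export
plot_transcriptome_map <- function(points) {
  ggplot2::ggplot(
    points,
    ggplot2::aes(x = .data$peak_cum_mb, y = .data$gene_cum_mb, colour = .data$tier)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(low = "#3366CC", intermediate = "#33A02C", high = "#E31A1C"),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "QTL peak position (cumulative Mb)",
      y = "Transcript position (cumulative Mb)",
      colour = "LRS tier"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qtl_heatmap <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$cum_mb, y = .data$probe, fill = .data$signed_lrs
    )) +
    ggplot2::geom_tile() +
    # D-haplotype-high in warm hues, B-haplotype-high in cool hues
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "grey95", high = "#B2182B", midpoint = 0
    ) +
    ggplot2::labs(
      x = "Genome position (cumulative Mb)", y = NULL,
      fill = "signed LRS"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @export
autoplot.cor_mat <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$probe1, y = .data$probe2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      midpoint = 0, limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a correlation network graph
#'
#' Lays out the nodes of a signed correlation edge list (force-directed via
#' igraph when available, circular otherwise) and draws edges coloured by the
#' signed correlation, from -1 (blue) to 1 (red).
#'
#' @param edges A `net_edges` tibble from [network_graph()].
#' @return A ggplot object.
#' @export
plot_network_graph <- function(edges) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  if (requireNamespace("igraph", quietly = TRUE) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    xy <- igraph::layout_with_fr(g)
    layout <- tibble::tibble(node = nodes, x = xy[, 1], y = xy[, 2])
  } else {
    theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
    layout <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  }
  seg <- edges |>
    dplyr::left_join(layout, by = c(source = "node")) |>
    dplyr::left_join(layout, by = c(target = "node"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        colour = .data$r
      ),
      linewidth = 0.8
    ) +
    ggplot2::geom_point(data = layout, ggplot2::aes(.data$x, .data$y), size = 8, colour = "lightsteelblue") +
    ggplot2::geom_text(data = layout, ggplot2::aes(.data$x, .data$y, label = .data$node), size = 3) +
    ggplot2::scale_colour_gradient2(
      low = "#2166AC", mid = "grey85", high = "#B2182B",
      midpoint = 0, limits = c(-1, 1)
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "r")
}
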