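#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout of the minimum-spanning network; node area
#' scales with haplotype count, tie edges are dashed, and edge labels
#' give the number of differences between connected haplotypes.
#'
#' @param object A `hap_network`.
#' @param label_edges Draw per-edge distance labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot hap_network
autoplot.hap_network <- function(object, label_edges = TRUE, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(edges)) {
    gr <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                        directed = FALSE,
                                        vertices = nodes$id)
    set.seed(1L)
    xy <- igraph::layout_with_fr(gr, weights = pmax(edges$dist, 0.5))
  } else {
    xy <- matrix(0, nrow(nodes), 2)
  }
  lay <- tibble(id = nodes$id, x = xy[, 1], y = xy[, 2],
                count = nodes$count)
  e <- dplyr::left_join(edges, lay, by = c(from = "id")) %>%
    rename(x0 = "x", y0 = "y") %>%
    dplyr::left_join(lay, by = c(to = "id")) %>%
    rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$tie_edge),
      colour = "grey40") +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$count),
      shape = 21, fill = "steelblue", colour = "black") +
    ggplot2::geom_text(
      data = lay, ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.4, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(size = "sequences")
  if (label_edges && nrow(e))
    p <- p + ggplot2::geom_text(
      data = e,
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                   y = (.data$y0 + .data$y1) / 2, label = .data$dist),
      size = 3, colour = "grey25")
  p
}

#' @export
plot.hap_network <- function(x, ...) print(autoplot.hap_network(x, ...))

#' Heatmap of pairwise linkage disequilibrium
#'
#' @param r2 Matrix from [ld_r2()].
#' @return A ggplot object.
#' @export
plot_ld <- function(r2) {
  d <- as_tibble(as.table(r2), .name_repair = ~c("a", "b", "r2"))
  ggplot2::ggplot(d, ggplot2::aes(.data$a, .data$b, fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Stacked genotype-class bars per resistance marker
#'
#' @param summary Output of [marker_summary()] (the `All` rows are used
#'   unless a single population is supplied).
#' @param population Population label to plot (default `"All"`).
#' @return A ggplot object.
#' @export
plot_marker_summary <- function(summary, population = "All") {
  d <- dplyr::filter(as_tibble(summary), .data$population == !!population) %>%
    tidyr::pivot_longer(c("pct_RR", "pct_RS", "pct_SS"),
                        names_to = "class", values_to = "pct") %>%
    mutate(class = factor(sub("pct_", "", .data$class),
                          levels = c("SS", "RS", "RR")))
  ggplot2::ggplot(d, ggplot2::aes(.data$marker_id, .data$pct,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(SS = "grey80", RS = "goldenrod",
                                          RR = "firebrick")) +
    ggplot2::labs(x = NULL, y = "% of genotyped samples",
                  fill = "genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
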