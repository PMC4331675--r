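view_layout <- function(nodes, edges, seed) {
  ig <- igraph::graph_from_data_frame(
    edges[, c("acc_a", "acc_b")], directed = FALSE, vertices = nodes)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig))
  tibble(node = nodes, x = xy[, 1L], y = xy[, 2L])
}

plot_network <- function(nodes, roles, edges, display_edges, seed, title) {
  lay <- view_layout(nodes, edges, seed)
  seg <- display_edges |>
    left_join(rename(lay, xa = "x", ya = "y"), by = c(acc_a = "node")) |>
    left_join(rename(lay, xb = "x", yb = "y"), by = c(acc_b = "node"))
  pts <- mutate(lay, role = roles[.data$node])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      color = "grey60", linewidth = 0.4) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$role,
                   size = .data$role == "main")) +
    ggplot2::geom_text(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1.1, size = 2.6) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 5, `FALSE` = 3), guide = "none") +
    ggplot2::scale_color_manual(values = c(
      main = "#2b6cb0", input_leaf = "#38a169", mediator = "#68d391",
      path = "#38a169", leaf = "#38a169")) +
    ggplot2::labs(title = title, color = "role") +
    ggplot2::theme_void()
}

#' Plot a subnetwork view
#'
#' Static ggplot2 companion to the HTML pages: force-directed layout with
#' main nodes enlarged and colored apart from leaves and mediators.
#'
#' @param object A `ppi_view` or `ppi_path_set`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_view
#' @export
autoplot.ppi_view <- function(object, seed = 0L, ...) {
  nodes <- object$style$node
  roles <- setNames(object$style$role, object$style$node)
  plot_network(nodes, roles, object$edges, object$display_edges, seed,
               sprintf("%d main / %d leaf / %d mediator node(s)",
                       length(object$main_nodes),
                       length(object$input_leaf_nodes),
                       length(object$mediator_nodes)))
}

#' @rdname autoplot.ppi_view
#' @method autoplot ppi_path_set
#' @export
autoplot.ppi_path_set <- function(object, seed = 0L, ...) {
  if (!length(object$paths)) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = sprintf("%s -> %s: unreachable",
                                           object$source, object$target)) +
             ggplot2::theme_void())
  }
  nodes <- sort(unique(unlist(object$paths)))
  roles <- setNames(ifelse(nodes %in% c(object$source, object$target),
                           "main", "path"), nodes)
  ev <- object$evidence
  plot_network(nodes, roles, ev, ev, seed,
               sprintf("%s -> %s: %d shortest path(s), total cost %.4g",
                       object$source, object$target, length(object$paths),
                       object$total_cost))
}
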