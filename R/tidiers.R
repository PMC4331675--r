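#' Tidy and summarize network objects
#'
#' broom-style methods so every result type drops into a dplyr pipeline:
#' `tidy()` returns one row per element (edge, path, node, or database
#' pair) and `glance()` a one-row summary.
#'
#' @param x A `ppi_graph`, `ppi_path_set`, `ppi_view`, or `ppi_overlap`.
#' @param ... Unused.
#' @return A tibble.
#' @name ppipath-tidiers
NULL

#' @rdname ppipath-tidiers
#' @method tidy ppi_graph
#' @export
tidy.ppi_graph <- function(x, ...) {
  x$edges
}

#' @rdname ppipath-tidiers
#' @method glance ppi_graph
#' @export
glance.ppi_graph <- function(x, ...) {
  n <- length(x$nodes)
  tibble(
    n_proteins = n,
    n_interactions = nrow(x$edges),
    n_self_interactions = sum(x$edges$acc_a == x$edges$acc_b),
    n_cost_overrides = sum(x$edges$cost_is_override),
    mean_cost = if (nrow(x$edges)) mean(x$edges$cost) else NA_real_,
    density = if (n > 1) sum(x$edges$acc_a != x$edges$acc_b) / (n * (n - 1) / 2)
              else NA_real_
  )
}

#' @rdname ppipath-tidiers
#' @method tidy ppi_path_set
#' @export
tidy.ppi_path_set <- function(x, ...) {
  if (!length(x$paths)) {
    return(tibble(rank = integer(0), n_steps = integer(0),
                  total_cost = numeric(0), path = character(0)))
  }
  tibble(
    rank = seq_along(x$paths),
    n_steps = lengths(x$paths) - 1L,
    total_cost = x$total_cost,
    path = vapply(x$paths, paste, character(1), collapse = " -> ")
  )
}

#' @rdname ppipath-tidiers
#' @method glance ppi_path_set
#' @export
glance.ppi_path_set <- function(x, ...) {
  tibble(
    source = x$source, target = x$target,
    reachable = !x$unreachable,
    total_cost = x$total_cost,
    n_paths = length(x$paths),
    n_steps_min = if (length(x$paths)) min(lengths(x$paths)) - 1L else NA_integer_,
    by_step = x$by_step,
    truncated = x$truncated
  )
}

#' @rdname ppipath-tidiers
#' @method tidy ppi_view
#' @export
tidy.ppi_view <- function(x, ...) {
  x$style
}

#' @rdname ppipath-tidiers
#' @method glance ppi_view
#' @export
glance.ppi_view <- function(x, ...) {
  tibble(
    n_main = length(x$main_nodes),
    n_input_leaves = length(x$input_leaf_nodes),
    n_mediators = length(x$mediator_nodes),
    n_edges = nrow(x$edges),
    n_display_edges = nrow(x$display_edges),
    sampled = x$sampled
  )
}

#' @rdname ppipath-tidiers
#' @method tidy ppi_overlap
#' @export
tidy.ppi_overlap <- function(x, ...) {
  dbs <- rownames(x$protein_counts)
  grid <- expand.grid(db_a = dbs, db_b = dbs, stringsAsFactors = FALSE)
  tibble(
    db_a = grid$db_a,
    db_b = grid$db_b,
    proteins = x$protein_counts[cbind(grid$db_a, grid$db_b)],
    interactions = x$interaction_counts[cbind(grid$db_a, grid$db_b)]
  ) |> arrange(.data$db_a, .data$db_b)
}

#' @rdname ppipath-tidiers
#' @method glance ppi_overlap
#' @export
glance.ppi_overlap <- function(x, ...) {
  tibble(
    n_databases = nrow(x$protein_counts),
    total_distinct_proteins = sum(x$distinct_proteins),
    total_distinct_interactions = sum(x$distinct_interactions)
  )
}
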