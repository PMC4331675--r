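new_view <- function(main_nodes, leaf_nodes, mediator_nodes, edges,
                     display_edges, sampled, paths = NULL,
                     unreachable = FALSE) {
  roles <- c(
    setNames(rep("main", length(main_nodes)), main_nodes),
    setNames(rep("input_leaf", length(leaf_nodes)), leaf_nodes),
    setNames(rep("mediator", length(mediator_nodes)), mediator_nodes)
  )
  # style classes only; concrete colors/sizes are chosen at render time
  style <- tibble(
    node = names(roles) %||% character(0),
    role = unname(roles),
    color_class = as.character(ifelse(roles == "main", "main", "leaf")),
    size_class = as.character(ifelse(roles == "main", "large", "small"))
  ) |> arrange(.data$node)
  structure(
    list(
      main_nodes = sort(main_nodes),
      input_leaf_nodes = sort(leaf_nodes),
      mediator_nodes = sort(mediator_nodes),
      edges = arrange(edges, .data$acc_a, .data$acc_b),
      display_edges = display_edges,
      sampled = sampled,
      style = style,
      paths = paths,
      unreachable = unreachable
    ),
    class = "ppi_view"
  )
}

view_edge_cols <- function(e) {
  select(e, "acc_a", "acc_b", "sources", "pmids", "string_score", "cost")
}

empty_view_edges <- function() {
  tibble(acc_a = character(0), acc_b = character(0), sources = character(0),
         pmids = character(0), string_score = integer(0), cost = numeric(0))
}

#' Neighborhood view of a single protein
#'
#' Builds the one-protein network view: the query protein as the single
#' main node with all its interaction partners as leaf nodes. When the
#' protein has more than `sample_size` interactions, the rendered graph
#' shows a uniform random sample of exactly `sample_size` of them (seeded,
#' so views are reproducible), while the full interaction set is kept for
#' the evidence table.
#'
#' @param graph A `ppi_graph`.
#' @param protein Protein name or accession.
#' @param mapping Optional `ppi_mapping` for name resolution.
#' @param sample_size Display budget for edges (default 100).
#' @param seed Seed for display sampling.
#' @return A `ppi_view`.
#' @export
neighborhood_view <- function(graph, protein, mapping = NULL,
                              sample_size = 100L, seed = 0L) {
  stopifnot(inherits(graph, "ppi_graph"))
  stopifnot_count(sample_size, "sample_size")
  acc <- resolve_or_miss(protein, mapping, "query")
  require_node(graph, acc)
  edges <- view_edge_cols(incident_edges(graph, acc)) |>
    arrange(.data$acc_a, .data$acc_b)
  sampled <- nrow(edges) > sample_size
  display_edges <- if (sampled) {
    keep <- withr::with_seed(seed, sort(sample.int(nrow(edges), sample_size)))
    edges[keep, ]
  } else {
    edges
  }
  leaves <- setdiff(unique(c(edges$acc_a, edges$acc_b)), acc)
  new_view(acc, leaves, character(0), edges, display_edges, sampled)
}

mediators_of <- function(graph, anchor_nodes, exclude) {
  counts <- list()
  for (m in anchor_nodes) {
    nb <- setdiff(unique(incident_edges(graph, m, include_self = FALSE)$neighbor),
                  exclude)
    for (v in nb) counts[[v]] <- (counts[[v]] %||% 0L) + 1L
  }
  sort(names(counts)[vapply(counts, function(k) k >= 2L, logical(1))])
}

edges_between <- function(graph, set_a, set_b) {
  e <- graph$edges
  hit <- (e$acc_a %in% set_a & e$acc_b %in% set_b) |
         (e$acc_a %in% set_b & e$acc_b %in% set_a)
  view_edge_cols(e[hit, ])
}

#' Multi-protein view with main/leaf designation and mediator proteins
#'
#' Renders a set of query proteins together. Proteins listed in `main` are
#' main nodes: all interactions among them are shown. The remaining query
#' proteins are input leaf nodes: only their interactions with main nodes
#' are shown. Because interactions are often bridged by scaffolding
#' proteins, any non-query protein interacting with at least two main
#' nodes is added as a mediator, with exactly its edges to main nodes.
#'
#' @param graph A `ppi_graph`.
#' @param proteins Character vector of query protein names/accessions.
#' @param main Subset of `proteins` to treat as main nodes (default: all).
#' @param mapping Optional `ppi_mapping` for name resolution.
#' @return A `ppi_view`.
#' @export
multi_view <- function(graph, proteins, main = proteins, mapping = NULL) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (length(proteins) < 1L) {
    abort("need at least one query protein", class = "ppipath_usage_error")
  }
  accs <- vapply(proteins, resolve_or_miss, character(1), mapping, "query")
  mains <- vapply(main, resolve_or_miss, character(1), mapping, "main")
  for (a in accs) require_node(graph, a)
  if (!all(mains %in% accs)) {
    abort("main proteins must be among the query proteins",
          class = "ppipath_usage_error")
  }
  mains <- intersect(accs, mains)
  if (length(mains) < 1L) {
    abort("at least one query protein must be designated a main node",
          class = "ppipath_usage_error")
  }
  accs <- unique(unname(accs))
  leaves <- setdiff(accs, mains)

  mm_edges <- edges_between(graph, mains, mains)
  leaf_edges <- edges_between(graph, leaves, mains)
  mediators <- mediators_of(graph, mains, exclude = accs)
  med_edges <- edges_between(graph, mediators, mains)

  edges <- distinct(bind_rows(mm_edges, leaf_edges, med_edges))
  edges <- arrange(edges, .data$acc_a, .data$acc_b)
  new_view(mains, leaves, mediators, edges, edges, sampled = FALSE)
}

#' View of a shortest-path result with mediator context
#'
#' Renders all enumerated shortest paths of a path set as a subnetwork:
#' every protein lying on any of the paths acts as a main node (all
#' interactions among path proteins are shown), and any off-path protein
#' interacting with at least two path proteins is added as a mediator —
#' surfacing slightly suboptimal routes around the optimal ones. Each
#' individual path is kept as highlighting metadata so a selected path can
#' be emphasized in the rendered page.
#'
#' @param graph A `ppi_graph`.
#' @param path_set A `ppi_path_set` from [shortest_paths()].
#' @return A `ppi_view` (empty, with the unreachable flag propagated, when
#'   the path set is unreachable).
#' @export
path_view <- function(graph, path_set) {
  stopifnot(inherits(graph, "ppi_graph"), inherits(path_set, "ppi_path_set"))
  if (path_set$unreachable || !length(path_set$paths)) {
    return(new_view(character(0), character(0), character(0),
                    empty_view_edges(), empty_view_edges(),
                    sampled = FALSE, paths = list(),
                    unreachable = path_set$unreachable))
  }
  path_nodes <- sort(unique(unlist(path_set$paths)))
  mm_edges <- edges_between(graph, path_nodes, path_nodes)
  mediators <- mediators_of(graph, path_nodes, exclude = path_nodes)
  med_edges <- edges_between(graph, mediators, path_nodes)
  edges <- distinct(bind_rows(mm_edges, med_edges))
  edges <- arrange(edges, .data$acc_a, .data$acc_b)
  new_view(path_nodes, character(0), mediators, edges, edges,
           sampled = FALSE, paths = path_set$paths)
}

#' @export
print.ppi_view <- function(x, ...) {
  cat(sprintf(paste0("<ppi_view> %d main, %d input leaf, %d mediator node(s); ",
                     "%d edge(s)%s%s\n"),
              length(x$main_nodes), length(x$input_leaf_nodes),
              length(x$mediator_nodes), nrow(x$edges),
              if (x$sampled) sprintf(" (%d displayed)", nrow(x$display_edges)) else "",
              if (isTRUE(x$unreachable)) " [unreachable]" else ""))
  invisible(x)
}
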