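#' Single-source shortest-path distances with all optimal predecessors
#'
#' Runs Dijkstra's algorithm from `source` over the cost-weighted,
#' undirected interaction graph and records, for every reached node, every
#' predecessor that lies on some minimal-cost route (ties recognized within
#' an absolute tolerance, since costs are sums of floating-point edge
#' costs). The resulting predecessor DAG compactly encodes *all* shortest
#' paths: backward traversal from any target enumerates them
#' ([enumerate_paths()]).
#'
#' With `by_step = TRUE` every edge counts 1 regardless of its cost, so
#' distances are hop counts and paths are minimum-step paths.
#' Self-loop edges are ignored: with all costs >= 1 they can never lie on a
#' shortest path.
#'
#' @param graph A `ppi_graph`.
#' @param source Source accession (must be a node).
#' @param by_step If `TRUE`, ignore costs and count steps.
#' @param tolerance Absolute tolerance for recognizing cost ties.
#' @return A `ppi_preds` object: `source`, `dist` (named numeric over
#'   reachable nodes), `preds` (named list of predecessor accessions),
#'   `by_step`.
#' @export
dijkstra_predecessors <- function(graph, source, by_step = FALSE,
                                  tolerance = 1e-9) {
  stopifnot(inherits(graph, "ppi_graph"))
  require_node(graph, source, what = "source protein")

  nodes <- graph$nodes
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  preds <- lapply(seq_len(n), function(i) character(0))
  dist[idx[[source]]] <- 0

  # O(n^2) selection; interaction networks handled here are small enough
  # that a heap buys nothing over vectorized min scans
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || is.infinite(dist[[u]]) || all(done)) break
    if (done[[u]]) break
    done[[u]] <- TRUE
    u_acc <- nodes[[u]]
    inc <- incident_edges(graph, u_acc, include_self = FALSE)
    if (!nrow(inc)) next
    w <- if (by_step) rep(1, nrow(inc)) else inc$cost
    for (k in seq_len(nrow(inc))) {
      v <- idx[[inc$neighbor[[k]]]]
      cand <- dist[[u]] + w[[k]]
      if (cand < dist[[v]] - tolerance) {
        dist[[v]] <- cand
        preds[[v]] <- u_acc
      } else if (abs(cand - dist[[v]]) <= tolerance) {
        preds[[v]] <- unique(c(preds[[v]], u_acc))
      }
    }
  }

  reached <- !is.infinite(dist)
  structure(
    list(
      source = source,
      dist = setNames(dist[reached], nodes[reached]),
      preds = setNames(preds[reached], nodes[reached]),
      by_step = by_step,
      tolerance = tolerance
    ),
    class = "ppi_preds"
  )
}

new_path_set <- function(source, target, total_cost, by_step, paths,
                         truncated, unreachable, evidence = NULL) {
  structure(
    list(
      source = source, target = target, total_cost = total_cost,
      by_step = by_step, paths = paths, truncated = truncated,
      unreachable = unreachable, evidence = evidence
    ),
    class = "ppi_path_set"
  )
}

# deterministic path order: fewer steps first, then lexicographic on the
# accession sequence
order_paths <- function(paths) {
  if (!length(paths)) return(paths)
  steps <- lengths(paths) - 1L
  key <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(steps, key)]
}

#' Enumerate all shortest paths to a target from a predecessor DAG
#'
#' Walks the predecessor relation backward from `target`, multiplying out
#' every tie, to list each distinct shortest path. When more than `cap`
#' paths exist, exactly `cap` are returned in deterministic sort order
#' (fewest steps first, then lexicographic) and the result is flagged
#' truncated. An unreachable target yields an empty, explicitly flagged
#' path set.
#'
#' @param dag A `ppi_preds` from [dijkstra_predecessors()].
#' @param target Target accession.
#' @param cap Maximum number of paths to return.
#' @return A `ppi_path_set`.
#' @export
enumerate_paths <- function(dag, target, cap = 100L) {
  stopifnot(inherits(dag, "ppi_preds"))
  stopifnot_count(cap, "cap")
  if (!target %in% names(dag$dist)) {
    return(new_path_set(dag$source, target, NA_real_, dag$by_step,
                        list(), truncated = FALSE, unreachable = TRUE))
  }
  walk_back <- function(node) {
    if (node == dag$source) return(list(node))
    ps <- dag$preds[[node]]
    unlist(
      lapply(ps, function(p) lapply(walk_back(p), function(pre) c(pre, node))),
      recursive = FALSE
    )
  }
  paths <- order_paths(walk_back(target))
  truncated <- length(paths) > cap
  if (truncated) paths <- paths[seq_len(cap)]
  new_path_set(dag$source, target, unname(dag$dist[[target]]), dag$by_step,
               paths, truncated = truncated, unreachable = FALSE)
}

path_edge_evidence <- function(graph, paths) {
  if (!length(paths)) {
    return(tibble(acc_a = character(0), acc_b = character(0),
                  sources = character(0), pmids = character(0),
                  string_score = integer(0), cost = numeric(0)))
  }
  pairs <- unique(bind_rows(lapply(paths, function(p) {
    if (length(p) < 2L) return(NULL)
    canonical_pair(p[-length(p)], p[-1L])
  })))
  if (!nrow(pairs) || !"acc_a" %in% names(pairs)) {
    return(tibble(acc_a = character(0), acc_b = character(0),
                  sources = character(0), pmids = character(0),
                  string_score = integer(0), cost = numeric(0)))
  }
  left_join(pairs, select(graph$edges, "acc_a", "acc_b", "sources", "pmids",
                          "string_score", "cost"),
            by = c("acc_a", "acc_b")) |>
    arrange(.data$acc_a, .data$acc_b)
}

#' All shortest interaction paths between two proteins
#'
#' Finds every cost-minimal (or, with `by_step = TRUE`, step-minimal)
#' interaction path between two proteins, with the database evidence
#' supporting each traversed edge attached. Inputs may be gene names or
#' accessions when a mapping table is supplied; an unresolvable name
#' raises a `ppipath_miss` condition naming which input failed.
#' `source == target` yields a single zero-length path.
#'
#' @param graph A `ppi_graph`.
#' @param source,target Protein names or accessions.
#' @param mapping Optional `ppi_mapping` used to resolve `source`/`target`.
#' @param by_step If `TRUE`, minimize the number of steps instead of cost.
#' @param cap Maximum number of paths to enumerate (default 100).
#' @param tolerance Absolute tolerance for cost ties.
#' @return A `ppi_path_set` with per-edge evidence.
#' @examples
#' tbl <- tibble::tibble(
#'   acc_a = c("P1", "P1", "P2"), acc_b = c("P2", "P3", "P3"),
#'   sources = "PINA", pmids = "12345678",
#'   string_score = NA_integer_, cost = NA_real_
#' )
#' g <- build_graph(tbl)
#' shortest_paths(g, "P1", "P3")
#' @export
shortest_paths <- function(graph, source, target, mapping = NULL,
                           by_step = FALSE, cap = 100L, tolerance = 1e-9) {
  stopifnot(inherits(graph, "ppi_graph"))
  src <- resolve_or_miss(source, mapping, "source")
  tgt <- resolve_or_miss(target, mapping, "target")
  require_node(graph, src, what = "source protein")
  require_node(graph, tgt, what = "target protein")
  if (src == tgt) {
    ps <- new_path_set(src, tgt, 0, by_step, list(src),
                       truncated = FALSE, unreachable = FALSE)
    ps$evidence <- path_edge_evidence(graph, ps$paths)
    return(ps)
  }
  dag <- dijkstra_predecessors(graph, src, by_step = by_step,
                               tolerance = tolerance)
  ps <- enumerate_paths(dag, tgt, cap = cap)
  ps$evidence <- path_edge_evidence(graph, ps$paths)
  ps
}

resolve_or_miss <- function(x, mapping, which_input) {
  if (is.null(mapping)) return(as.character(x))
  acc <- resolve_protein(x, mapping)
  if (is.na(acc)) {
    miss(sprintf("%s protein '%s' cannot be mapped to a UniProtKB accession",
                 which_input, x))
  }
  acc
}

#' Screen shortest paths from one protein to every reachable protein
#'
#' One Dijkstra run from the source, then per-target enumeration, so a
#' research group focused on one protein can browse pre-computed shortest
#' paths to every other protein in the network. Use
#' [write_path_atlas()] to shard the result into one browsable document
#' per target plus an index.
#'
#' @inheritParams shortest_paths
#' @return A named list (one `ppi_path_set` per reachable target, the
#'   source itself excluded), of class `ppi_path_atlas`.
#' @export
single_source <- function(graph, source, mapping = NULL, by_step = FALSE,
                          cap = 100L, tolerance = 1e-9) {
  stopifnot(inherits(graph, "ppi_graph"))
  src <- resolve_or_miss(source, mapping, "source")
  require_node(graph, src, what = "source protein")
  dag <- dijkstra_predecessors(graph, src, by_step = by_step,
                               tolerance = tolerance)
  targets <- setdiff(names(dag$dist), src)
  targets <- targets[order(dag$dist[targets], targets)]
  out <- lapply(targets, function(tgt) {
    ps <- enumerate_paths(dag, tgt, cap = cap)
    ps$evidence <- path_edge_evidence(graph, ps$paths)
    ps
  })
  structure(setNames(out, targets), class = "ppi_path_atlas",
            source = src, by_step = by_step)
}

#' @export
print.ppi_path_set <- function(x, ...) {
  if (x$unreachable) {
    cat(sprintf("<ppi_path_set> %s -> %s: unreachable\n", x$source, x$target))
    return(invisible(x))
  }
  mode <- if (x$by_step) "steps" else "cost"
  cat(sprintf("<ppi_path_set> %s -> %s: %d shortest path(s), total %s %.6g%s\n",
              x$source, x$target, length(x$paths), mode, x$total_cost,
              if (x$truncated) " (truncated)" else ""))
  for (p in head(x$paths, 5L)) cat("  ", paste(p, collapse = " - "), "\n")
  if (length(x$paths) > 5L) cat(sprintf("  ... and %d more\n", length(x$paths) - 5L))
  invisible(x)
}

#' @export
print.ppi_path_atlas <- function(x, ...) {
  cat(sprintf("<ppi_path_atlas> source %s: shortest paths to %d protein(s)\n",
              attr(x, "source"), length(x)))
  invisible(x)
}
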