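#' Edge cost under the confidence-based cost model
#'
#' Shortest-path search treats each interaction edge as having a "cost"
#' >= 1 quantifying how unfavorable the interaction is. Curated evidence
#' (PINA, iRefIndex, or any private source with literature support) costs
#' exactly 1. STRING evidence, being partly predicted, is penalized by its
#' combined confidence score `s` (an integer in 1..999):
#'
#'   cost(s) = max(1, log_100(1000 - s))
#'
#' so a score of 900 gives exactly 1 (log_100 of 100) and lower-confidence
#' edges cost more, up to log_100(999) ~ 1.4998 at score 1. When an edge
#' carries evidence from several sources, its cost is the minimum over the
#' per-source costs — the most favorable evidence governs the search — and
#' a user override (>= 1) always wins.
#'
#' @param sources Character vector: the databases supporting this edge.
#' @param string_score Integer STRING combined score in (0, 1000); must be
#'   present iff `"STRING"` is among `sources`.
#' @param override Optional numeric cost >= 1 assigned by the user.
#' @return A single numeric cost, always >= 1.
#' @examples
#' edge_cost("PINA")                     # 1
#' edge_cost("STRING", string_score = 900)  # exactly 1
#' edge_cost("STRING", string_score = 700)  # log100(300) ~ 1.2386
#' edge_cost(c("STRING", "iRefIndex"), string_score = 700)  # min rule: 1
#' @export
edge_cost <- function(sources, string_score = NA_integer_, override = NULL) {
  if (length(sources) < 1L) {
    abort("an edge needs at least one evidence source", class = "ppipath_domain_error")
  }
  if (!is.null(override)) {
    if (!is.numeric(override) || length(override) != 1L || is.na(override) ||
        override < 1) {
      abort("cost override must be a single number >= 1", class = "ppipath_domain_error")
    }
    return(as.numeric(override))
  }
  has_string <- "STRING" %in% sources
  if (has_string) {
    if (is.na(string_score)) {
      abort("STRING evidence requires a combined score", class = "ppipath_domain_error")
    }
    if (string_score <= 0 || string_score >= 1000) {
      abort("STRING score must lie strictly between 0 and 1000",
            class = "ppipath_domain_error")
    }
  } else if (!is.na(string_score)) {
    abort("a STRING score without STRING evidence is inconsistent",
          class = "ppipath_domain_error")
  }
  costs <- c(
    if (any(sources != "STRING")) 1,
    if (has_string) max(1, log(1000 - as.numeric(string_score), base = 100))
  )
  min(costs)
}

#' Build an evidence-annotated PPI graph
#'
#' Turns a standardized interaction table into an undirected graph keyed by
#' accession: one edge per table row, with its supporting sources, PubMed
#' IDs, STRING score, and the cost computed by [edge_cost()] (honoring any
#' per-row override in the `cost` column).
#'
#' @param table A standardized interaction tibble (see [read_standard()]).
#' @return A `ppi_graph`: sorted node vector, edge tibble (with `cost` and
#'   `cost_is_override`), and an adjacency index.
#' @export
build_graph <- function(table) {
  validate_standard_table(table)
  cost_is_override <- !is.na(table$cost)
  cost <- vapply(seq_len(nrow(table)), function(i) {
    edge_cost(split_sources(table$sources[[i]]),
              string_score = table$string_score[[i]],
              override = if (cost_is_override[[i]]) table$cost[[i]] else NULL)
  }, numeric(1))
  edges <- tibble(
    acc_a = table$acc_a,
    acc_b = table$acc_b,
    sources = table$sources,
    pmids = table$pmids,
    string_score = table$string_score,
    cost = cost,
    cost_is_override = cost_is_override
  )
  nodes <- sort(unique(c(edges$acc_a, edges$acc_b)))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), function(x) integer(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$acc_a[[i]]; b <- edges$acc_b[[i]]
    adj[[a]] <- c(adj[[a]], i)
    if (b != a) adj[[b]] <- c(adj[[b]], i)
  }
  structure(list(nodes = nodes, edges = edges, adj = adj), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  edge cost: min %.4g, max %.4g; %d cost override(s)\n",
                min(x$edges$cost), max(x$edges$cost), sum(x$edges$cost_is_override)))
  }
  invisible(x)
}

graph_has_node <- function(graph, accession) {
  accession %in% graph$nodes
}

require_node <- function(graph, accession, what = "protein") {
  if (!graph_has_node(graph, accession)) {
    sugg <- graph$nodes[head(order(utils::adist(accession, graph$nodes)), 3L)]
    miss(sprintf("%s '%s' is not in the network; nearest node names: %s",
                 what, accession, paste(sugg, collapse = ", ")))
  }
  invisible(accession)
}

# neighbor table for one node: one row per incident edge (self-loops excluded
# unless include_self), with the partner accession and the edge evidence
incident_edges <- function(graph, accession, include_self = TRUE) {
  idx <- graph$adj[[accession]]
  e <- graph$edges[idx, ]
  partner <- ifelse(e$acc_a == accession, e$acc_b, e$acc_a)
  out <- mutate(e, neighbor = partner, edge_idx = idx)
  if (!include_self) out <- filter(out, .data$neighbor != accession)
  out
}

#' Interaction partners of a protein
#'
#' Exact adjacency of one protein with per-edge evidence attached, the
#' content of the evidence table shown alongside a neighborhood view. An
#' unknown accession raises a classed miss condition (`ppipath_miss`)
#' carrying nearest-name suggestions rather than a plain error.
#'
#' @param graph A `ppi_graph`.
#' @param accession A node accession (resolve names first via
#'   [resolve_protein()]).
#' @return Tibble with one row per interaction: `neighbor`, `sources`,
#'   `pmids`, `string_score`, `cost`.
#' @export
neighbors <- function(graph, accession) {
  stopifnot(inherits(graph, "ppi_graph"))
  require_node(graph, accession)
  inc <- incident_edges(graph, accession)
  select(inc, "neighbor", "sources", "pmids", "string_score", "cost") |>
    arrange(.data$neighbor)
}
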