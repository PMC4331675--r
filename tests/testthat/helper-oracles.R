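# Independent oracles and generators used across the suite. The path oracle
# enumerates every simple path by depth-first search and keeps the
# cost-minimal ones; it shares no code with the package's Dijkstra engine.

brute_force_shortest <- function(edges, source, target, by_step = FALSE,
                                 tol = 1e-9) {
  nodes <- unique(c(edges$acc_a, edges$acc_b))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) NULL)
  for (i in seq_len(nrow(edges))) {
    a <- edges$acc_a[[i]]; b <- edges$acc_b[[i]]
    if (a == b) next
    w <- if (by_step) 1 else edges$cost[[i]]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w))
  }
  found <- list()
  dfs <- function(node, visited, cost, path) {
    if (node == target) {
      found[[length(found) + 1L]] <<- list(path = path, cost = cost)
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      v <- nb$to[[k]]
      if (v %in% visited) next
      dfs(v, c(visited, v), cost + nb$w[[k]], c(path, v))
    }
  }
  if (!(source %in% nodes) || !(target %in% nodes)) {
    return(list(cost = NA_real_, paths = list()))
  }
  if (source == target) return(list(cost = 0, paths = list(source)))
  dfs(source, source, 0, source)
  if (!length(found)) return(list(cost = NA_real_, paths = list()))
  costs <- vapply(found, `[[`, numeric(1), "cost")
  best <- min(costs)
  paths <- lapply(found[costs <= best + tol], `[[`, "path")
  steps <- lengths(paths) - 1L
  key <- vapply(paths, paste, character(1), collapse = "\r")
  list(cost = best, paths = paths[order(steps, key)])
}

# random standardized interaction table over n nodes (no file round trip);
# mixes curated and STRING evidence and occasional cost overrides
rand_table <- function(n_nodes, n_edges, seed, p_override = 0) {
  withr::with_seed(seed, {
    acc <- sprintf("N%03d", seq_len(n_nodes))
    all_pairs <- utils::combn(n_nodes, 2L)
    n_edges <- min(n_edges, ncol(all_pairs))
    picked <- all_pairs[, sample.int(ncol(all_pairs), n_edges), drop = FALSE]
    src_choice <- sample(c("PINA", "iRefIndex", "STRING", "PINA;STRING"),
                         n_edges, replace = TRUE)
    has_string <- grepl("STRING", src_choice)
    score <- ifelse(has_string, sample(500:999, n_edges, replace = TRUE),
                    NA_integer_)
    cost <- ifelse(stats::runif(n_edges) < p_override,
                   round(stats::runif(n_edges, 1, 3), 3), NA_real_)
    tibble::tibble(
      acc_a = acc[picked[1L, ]],
      acc_b = acc[picked[2L, ]],
      sources = src_choice,
      pmids = ifelse(has_string & src_choice == "STRING", "",
                     as.character(sample(1e7:4e7, n_edges))),
      string_score = as.integer(score),
      cost = cost
    )
  })
}

expect_graph_equal <- function(g1, g2) {
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
}

# tiny mapping fixture writer used by parser/mapping tests
write_tmp_mapping <- function(rows) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("accession\treviewed\tgene_name\tsynonyms\tsecondary_accessions",
               rows), tf)
  tf
}
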