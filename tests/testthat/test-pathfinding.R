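curated_tbl <- function(a, b, cost = NA_real_) {
  p <- canonical_pair(a, b)
  tibble::tibble(acc_a = p$acc_a, acc_b = p$acc_b, sources = "PINA",
                 pmids = "1", string_score = NA_integer_,
                 cost = rep(cost, length.out = length(a))) |>
    dplyr::arrange(acc_a, acc_b)
}

to_igraph <- function(g) {
  igraph::graph_from_data_frame(
    cbind(g$edges[g$edges$acc_a != g$edges$acc_b, c("acc_a", "acc_b")],
          weight = g$edges$cost[g$edges$acc_a != g$edges$acc_b]),
    directed = FALSE, vertices = g$nodes)
}

test_that("a direct edge beats a two-hop detour; ties record both predecessors", {
  g <- build_graph(curated_tbl(c("A", "B", "A"), c("B", "C", "C")))
  dag <- dijkstra_predecessors(g, "A")
  expect_identical(unname(dag$dist["C"]), 1)
  expect_identical(dag$preds[["C"]], "A")

  sq <- build_graph(curated_tbl(c("A", "B", "A", "C"), c("B", "D", "C", "D")))
  dag2 <- dijkstra_predecessors(sq, "A")
  expect_identical(unname(dag2$dist["D"]), 2)
  expect_setequal(dag2$preds[["D"]], c("B", "C"))
  expect_error(dijkstra_predecessors(sq, "NOPE"), class = "ppipath_miss")
})

test_that("distances agree with an independent shortest-path oracle on random graphs", {
  for (seed in c(1, 2, 3)) {
    g <- build_graph(rand_table(50, 120, seed = seed, p_override = 0.15))
    src <- g$nodes[[1]]
    dag <- dijkstra_predecessors(g, src)
    d_or <- igraph::distances(to_igraph(g), v = src)[1, ]
    reach <- names(d_or)[is.finite(d_or)]
    expect_setequal(names(dag$dist), reach)
    expect_equal(dag$dist[reach], d_or[reach], tolerance = 1e-9)
  }
})

test_that("predecessor distances are consistent and satisfy the triangle inequality", {
  g <- build_graph(rand_table(40, 90, seed = 8))
  dag <- dijkstra_predecessors(g, g$nodes[[5]])
  for (v in names(dag$preds)) {
    for (p in dag$preds[[v]]) {
      e <- dplyr::filter(g$edges, acc_a == min(p, v), acc_b == max(p, v))
      expect_lt(abs(dag$dist[[p]] + e$cost[[1]] - dag$dist[[v]]), 1e-9)
      expect_lt(dag$dist[[p]], dag$dist[[v]])  # acyclic under increasing dist
    }
  }
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$acc_a[[i]]; b <- g$edges$acc_b[[i]]
    if (a %in% names(dag$dist) && b %in% names(dag$dist)) {
      expect_lte(dag$dist[[b]], dag$dist[[a]] + g$edges$cost[[i]] + 1e-9)
    }
  }
})

test_that("layered fixtures enumerate exactly the product of interior widths", {
  cases <- list(
    list(layers = c(1, 2, 1), n = 2L, cost = 2),
    list(layers = c(1, 3, 2, 1), n = 6L, cost = 3),
    list(layers = c(1, 1), n = 1L, cost = 1)
  )
  for (cs in cases) {
    b <- gen_path_graph(cs$layers, seed = 4)
    g <- run_fixture_pipeline(b)$graph
    ps <- shortest_paths(g, b$source, b$sink)
    expect_identical(length(ps$paths), cs$n)
    expect_identical(b$n_paths, cs$n)
    expect_identical(ps$total_cost, cs$cost)
    expect_false(ps$truncated)
    # deterministic sort: fewer steps first, then lexicographic
    keys <- vapply(ps$paths, paste, character(1), collapse = "\r")
    expect_identical(keys, sort(keys, method = "radix"))
  }
})

test_that("enumeration caps at the limit and flags truncation", {
  b <- gen_path_graph(c(1, 3, 3, 3, 3, 3, 1), seed = 1)  # 243 paths
  g <- run_fixture_pipeline(b)$graph
  dag <- dijkstra_predecessors(g, b$source)
  full <- enumerate_paths(dag, b$sink, cap = 300L)
  expect_identical(length(full$paths), 243L)
  capped <- enumerate_paths(dag, b$sink, cap = 100L)
  expect_identical(length(capped$paths), 100L)
  expect_true(capped$truncated)
  expect_identical(capped$paths, full$paths[1:100])
})

test_that("every enumerated path re-costs to the optimal distance edge by edge", {
  g <- build_graph(rand_table(30, 70, seed = 12, p_override = 0.2))
  dag <- dijkstra_predecessors(g, g$nodes[[1]])
  targets <- utils::tail(names(dag$dist), 5)
  edge_lookup <- stats::setNames(g$edges$cost,
                                 paste(g$edges$acc_a, g$edges$acc_b))
  for (tgt in targets) {
    ps <- enumerate_paths(dag, tgt)
    for (p in ps$paths) {
      pairs <- canonical_pair(p[-length(p)], p[-1])
      total <- sum(edge_lookup[paste(pairs$acc_a, pairs$acc_b)])
      expect_lt(abs(total - dag$dist[[tgt]]), 1e-9)
      expect_identical(anyDuplicated(p), 0L)  # simple path
    }
  }
})

test_that("enumerated path sets equal brute-force all-simple-paths filtering", {
  sizes <- c(6L, 8L, 10L, 11L, 12L, 14L)
  for (seed in 41:46) {
    tbl <- rand_table(8, sizes[[seed - 40L]], seed = seed, p_override = 0.3)
    g <- build_graph(tbl)
    src <- g$nodes[[1]]
    dag <- dijkstra_predecessors(g, src)
    for (tgt in setdiff(g$nodes, src)) {
      oracle <- brute_force_shortest(g$edges, src, tgt)
      ps <- enumerate_paths(dag, tgt, cap = 1000L)
      if (!length(oracle$paths)) {
        expect_true(ps$unreachable)
      } else {
        expect_equal(ps$total_cost, oracle$cost, tolerance = 1e-9)
        expect_identical(ps$paths, oracle$paths)
      }
    }
  }
})

test_that("step mode counts hops like breadth-first search", {
  for (seed in c(5, 6)) {
    g <- build_graph(rand_table(40, 80, seed = seed))
    src <- g$nodes[[3]]
    dag <- dijkstra_predecessors(g, src, by_step = TRUE)
    hops <- igraph::distances(to_igraph(g), v = src, weights = NA)[1, ]
    reach <- names(hops)[is.finite(hops)]
    expect_setequal(names(dag$dist), reach)
    expect_equal(dag$dist[reach], hops[reach])
  }
})

test_that("cost mode and step mode can disagree, each optimal in its metric", {
  # direct edge with an unfavorable override vs a cheap two-hop detour
  tbl <- dplyr::bind_rows(
    curated_tbl("A", "B", cost = 3),
    curated_tbl(c("A", "M"), c("M", "B"))
  ) |> dplyr::arrange(acc_a, acc_b)
  g <- build_graph(tbl)
  by_cost <- shortest_paths(g, "A", "B")
  expect_identical(by_cost$paths, list(c("A", "M", "B")))
  expect_identical(by_cost$total_cost, 2)
  by_hop <- shortest_paths(g, "A", "B", by_step = TRUE)
  expect_identical(by_hop$paths, list(c("A", "B")))
  expect_identical(by_hop$total_cost, 1)
})

test_that("degenerate and unreachable queries are explicit, never errors", {
  tbl <- dplyr::bind_rows(curated_tbl("A", "B"), curated_tbl("C", "D"))
  g <- build_graph(dplyr::arrange(tbl, acc_a, acc_b))
  same <- shortest_paths(g, "A", "A")
  expect_identical(same$paths, list("A"))
  expect_identical(same$total_cost, 0)
  un <- shortest_paths(g, "A", "D")
  expect_true(un$unreachable)
  expect_identical(length(un$paths), 0L)
})

test_that("name resolution failures name the offending input", {
  b <- gen_random_ppi(10, 15, seed = 2, decoy_fraction = 0)
  res <- run_fixture_pipeline(b)
  err <- tryCatch(
    shortest_paths(res$graph, "NOSUCH", res$graph$nodes[[1]],
                   mapping = res$mapping),
    condition = identity)
  expect_s3_class(err, "ppipath_miss")
  expect_match(conditionMessage(err), "NOSUCH")
  expect_match(conditionMessage(err), "source")
})

test_that("single-source screening matches independent pairwise runs", {
  b <- gen_random_ppi(50, 120, seed = 42)
  g <- run_fixture_pipeline(b)$graph
  atlas <- single_source(g, g$nodes[[1]])
  expect_gt(length(atlas), 0L)
  some <- names(atlas)[seq(1, length(atlas), length.out = 8)]
  for (tgt in some) {
    pair <- shortest_paths(g, g$nodes[[1]], tgt)
    expect_equal(atlas[[tgt]]$total_cost, pair$total_cost, tolerance = 1e-9)
    expect_identical(atlas[[tgt]]$paths, pair$paths)
  }
})

test_that("hub screening yields one-step paths from the center, two-step between leaves", {
  h <- gen_hub(12, seed = 9)
  g <- run_fixture_pipeline(h)$graph
  from_center <- single_source(g, h$center)
  expect_identical(length(from_center), 12L)
  expect_true(all(vapply(from_center, function(p) lengths(p$paths) == 2L,
                         logical(1))))
  from_leaf <- single_source(g, "P00001")
  expect_identical(length(from_leaf$P00000$paths[[1]]), 2L)
  other_leaves <- setdiff(names(from_leaf), h$center)
  expect_true(all(vapply(from_leaf[other_leaves],
                         function(p) length(p$paths) == 1L &&
                           length(p$paths[[1]]) == 3L, logical(1))))
})
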