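mk_records <- function(id_a, id_b, source_db = "PINA", pmids = NULL,
                       string_score = NA_integer_) {
  n <- length(id_a)
  tibble::tibble(
    id_a = id_a, id_b = id_b, source_db = source_db,
    pmids = pmids %||% rep(list(integer(0)), n),
    string_score = rep(as.integer(string_score), length.out = n)
  )
}

identity_mapping <- function(accs) {
  build_mapping(write_tmp_mapping(
    sprintf("%s\tyes\tG_%s\t\t", accs, accs)))
}

test_that("unordered duplicates collapse to one canonical interaction", {
  m <- identity_mapping(c("A", "B"))
  set <- canonicalize(mk_records(c("A", "B"), c("B", "A"),
                                 pmids = list(1L, 2L)), m)
  expect_identical(nrow(set$interactions), 1L)
  expect_identical(set$interactions$acc_a, "A")
  expect_identical(set$interactions$acc_b, "B")
  expect_identical(set$interactions$pmids[[1]], c(1L, 2L))
  expect_identical(set$discarded, 0L)
})

test_that("records with unmappable interactors are discarded and counted", {
  m <- identity_mapping(c("A", "B"))
  set <- canonicalize(mk_records(c("A", "NOPE"), c("NOPE", "A"),
                                 pmids = list(1L, 2L)), m)
  expect_identical(nrow(set$interactions), 0L)
  expect_identical(set$discarded, 2L)
})

test_that("mixed-source record sets are a usage error", {
  m <- identity_mapping(c("A", "B"))
  recs <- dplyr::bind_rows(mk_records("A", "B"),
                           mk_records("A", "B", source_db = "STRING",
                                      string_score = 900L))
  expect_error(canonicalize(recs, m), class = "ppipath_usage_error")
})

test_that("combining merges evidence and counts overlaps like set algebra", {
  m <- identity_mapping(c("A", "B", "C"))
  pina <- canonicalize(mk_records(c("A", "A"), c("B", "C"),
                                  pmids = list(1L, 2L)), m)
  string <- canonicalize(mk_records("A", "B", source_db = "STRING",
                                    string_score = 800L), m)
  res <- combine_ppi(list(pina, string))
  shared <- dplyr::filter(res$table, acc_a == "A", acc_b == "B")
  expect_identical(shared$sources, "PINA;STRING")
  expect_identical(shared$string_score, 800L)
  ov <- res$overlaps
  expect_identical(ov$interaction_counts["PINA", "STRING"], 1L)
  expect_identical(ov$interaction_counts["PINA", "PINA"], 2L)  # diagonal = per-db
  expect_identical(unname(ov$distinct_interactions["PINA"]), 1L)
  expect_identical(unname(ov$distinct_interactions["STRING"]), 0L)
  expect_identical(ov$protein_counts["PINA", "STRING"], 2L)
})

test_that("three disjoint single-edge sets have zero pairwise overlap", {
  m <- identity_mapping(c("A", "B", "C", "D", "E", "F"))
  sets <- list(
    canonicalize(mk_records("A", "B"), m),
    canonicalize(mk_records("C", "D", source_db = "iRefIndex"), m),
    canonicalize(mk_records("E", "F", source_db = "STRING",
                            string_score = 900L), m)
  )
  ov <- combine_ppi(sets)$overlaps
  expect_true(all(ov$distinct_interactions == 1L))
  off_diag <- ov$interaction_counts
  diag(off_diag) <- 0L
  expect_true(all(off_diag == 0L))
  expect_error(combine_ppi(list(sets[[1]], sets[[1]])),
               class = "ppipath_usage_error")
})

test_that("overlap summary equals brute-force set recomputation on a mixed fixture", {
  b <- gen_random_ppi(50, 120, seed = 42)
  res <- run_fixture_pipeline(b)
  # independent oracle: naive set operations over the per-source pair sets
  sets <- res$sets
  names(sets) <- vapply(sets, `[[`, character(1), "source_db")
  pair_sets <- lapply(sets, function(s)
    paste(s$interactions$acc_a, s$interactions$acc_b))
  prot_sets <- lapply(sets, function(s)
    unique(c(s$interactions$acc_a, s$interactions$acc_b)))
  ov <- res$overlaps
  for (i in names(sets)) {
    for (j in names(sets)) {
      expect_identical(ov$interaction_counts[i, j],
                       length(intersect(pair_sets[[i]], pair_sets[[j]])))
      expect_identical(ov$protein_counts[i, j],
                       length(intersect(prot_sets[[i]], prot_sets[[j]])))
    }
    others_p <- unique(unlist(pair_sets[setdiff(names(sets), i)]))
    expect_identical(unname(ov$distinct_interactions[i]),
                     sum(!(pair_sets[[i]] %in% others_p)))
  }
  expect_identical(ov, b$truth_overlaps)
})

test_that("conservation and inclusion-exclusion hold; combine is order invariant", {
  for (seed in 1:5) {
    b <- gen_random_ppi(30, 60, seed = seed)
    res <- run_fixture_pipeline(b)
    sets <- res$sets
    pair_sets <- lapply(sets, function(s)
      paste(s$interactions$acc_a, s$interactions$acc_b))
    expect_identical(nrow(res$table), length(unique(unlist(pair_sets))))
    ov <- res$overlaps
    for (db in rownames(ov$interaction_counts)) {
      per_db <- ov$interaction_counts[db, db]
      k <- which(vapply(sets, `[[`, character(1), "source_db") == db)
      others <- unique(unlist(pair_sets[-k]))
      shared <- sum(pair_sets[[k]] %in% others)
      expect_identical(per_db, unname(ov$distinct_interactions[db]) + shared)
    }
    perm <- combine_ppi(rev(sets))
    expect_identical(perm$table, res$table)
    expect_identical(perm$overlaps, ov)
  }
})

test_that("self-interactions are retained and counted", {
  m <- identity_mapping(c("A", "B"))
  set <- canonicalize(mk_records(c("A", "A"), c("A", "B"),
                                 pmids = list(1L, 2L)), m)
  res <- combine_ppi(list(set))
  expect_identical(nrow(res$table), 2L)
  expect_true(any(res$table$acc_a == res$table$acc_b))
  expect_identical(res$overlaps$interaction_counts["PINA", "PINA"], 2L)
})

test_that("private data joins the combination under its own source label", {
  m <- identity_mapping(c("A", "B", "C"))
  pina <- canonicalize(mk_records("A", "B", pmids = list(5L)), m)
  mine <- canonicalize(mk_records("B", "C", source_db = "MyLab",
                                  pmids = list(9L)), m)
  res <- combine_ppi(list(pina, mine))
  expect_setequal(rownames(res$overlaps$interaction_counts), c("PINA", "MyLab"))
  g <- build_graph(res$table)
  expect_identical(g$edges$cost, c(1, 1))  # private curated data costs 1
})
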