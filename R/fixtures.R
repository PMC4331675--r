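PINA_HEADER <- paste(
  "ID(s) interactor A", "ID(s) interactor B", "Alt. ID(s) interactor A",
  "Alt. ID(s) interactor B", "Publication Identifier(s)", "Source database(s)",
  sep = "\t")

IREF_HEADER <- paste(
  "#uidA", "uidB", "altA", "altB", "aliasA", "aliasB", "pmids", "method",
  "sourcedb", sep = "\t")

STRING_SPECIES_PREFIX <- "9606."

fake_pmids <- function(k) {
  # deterministic under the surrounding seed; IDs carry no semantic meaning
  sort(sample.int(30000000L, k) + 9999999L)
}

pina_line <- function(id_a, id_b, pmids) {
  paste(id_a, id_b, "-", "-",
        paste0("pubmed:", pmids, collapse = "|"),
        'psi-mi:"MI:0469"(IntAct)', sep = "\t")
}

iref_line <- function(id_a, id_b, pmids) {
  paste(id_a, id_b, "-", "-", "-", "-",
        paste0("pubmed:", pmids, collapse = "|"),
        "MI:0018", "intact", sep = "\t")
}

new_fixture <- function(dir, truth_table, truth_overlaps, seed, counts,
                        sources_present, extras = list()) {
  structure(
    c(list(
      dir = dir,
      pina_path = file.path(dir, "pina.tsv"),
      iref_path = file.path(dir, "irefindex.tsv"),
      string_links_path = file.path(dir, "string_links.txt"),
      string_alias_path = file.path(dir, "string_aliases.tsv"),
      mapping_path = file.path(dir, "mapping.tsv"),
      truth_table = truth_table,
      truth_graph = build_graph(truth_table),
      truth_overlaps = truth_overlaps,
      seed = seed,
      counts = counts,
      sources_present = sources_present
    ), extras),
    class = "ppi_fixture"
  )
}

#' @export
print.ppi_fixture <- function(x, ...) {
  cat(sprintf("<ppi_fixture> seed %d, %d proteins, %d interactions; sources: %s\n  dir: %s\n",
              x$seed, length(x$truth_graph$nodes), nrow(x$truth_table),
              paste(x$sources_present, collapse = ", "), x$dir))
  invisible(x)
}

# brute-force overlap accounting straight from the generator's bookkeeping
overlaps_from_bookkeeping <- function(membership, pair_keys) {
  dbs <- sort(names(membership), method = "radix")
  pair_sets <- lapply(membership, function(m) pair_keys[m])
  protein_sets <- lapply(membership, function(m) {
    unique(unlist(strsplit(pair_keys[m], "\r", fixed = TRUE)))
  })
  names(pair_sets) <- names(protein_sets) <- names(membership)
  count <- function(sets) {
    m <- matrix(0L, length(dbs), length(dbs), dimnames = list(dbs, dbs))
    for (i in dbs) for (j in dbs) m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    d <- vapply(dbs, function(db) {
      others <- unique(unlist(sets[setdiff(dbs, db)]))
      sum(!(sets[[db]] %in% others))
    }, integer(1))
    list(m = m, d = d)
  }
  pr <- count(protein_sets[dbs])
  pa <- count(pair_sets[dbs])
  structure(
    list(protein_counts = pr$m, interaction_counts = pa$m,
         distinct_proteins = pr$d, distinct_interactions = pa$d),
    class = "ppi_overlap"
  )
}

write_fixture_mapping <- function(accessions, gene_names, reviewed, path) {
  write_mapping(
    tibble(
      accession = accessions,
      reviewed = reviewed,
      gene_name = gene_names,
      synonyms = paste0("SYN_", gene_names),
      secondary_accessions = ""
    ),
    path
  )
}

#' Generate a random synthetic PPI fixture
#'
#' Writes a complete set of synthetic input files — PINA- and
#' iRefIndex-style interaction tables, a STRING links + alias pair, and a
#' UniProtKB-style mapping file — describing one random interaction
#' network, together with the ground-truth standardized table, graph, and
#' overlap summary implied by the generator's own bookkeeping. Running the
#' parse → map → combine pipeline over the files reproduces the truth
#' exactly, which makes every downstream module testable without any
#' database download. Generation is fully deterministic under `seed`
#' (byte-identical files on regeneration).
#'
#' Each sampled edge joins each source independently with the probability
#' given in `source_mix` (an edge that draws no source is assigned one in
#' proportion to the mix). STRING edges carry integer combined scores
#' uniform in `score_range`; curated records carry 1-3 synthetic PubMed
#' IDs, and around 10% of curated records are written twice with extra
#' PubMed IDs to exercise within-source deduplication. A fraction of
#' records (default 5%) reference unmappable decoy proteins to exercise
#' the discard rule.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param n_edges Number of distinct interactions (<= `choose(n_proteins, 2)`).
#' @param source_mix Named inclusion probabilities for `PINA`, `iRefIndex`,
#'   `STRING` (each in `[0, 1]`; at least one positive).
#' @param seed Integer seed.
#' @param dir Output directory (created; default a fresh tempdir).
#' @param decoy_fraction Fraction of records rewritten against unmappable
#'   decoy names.
#' @param score_range Inclusive integer range for STRING combined scores;
#'   defaults to `c(700, 999)` so all synthetic STRING rows survive the
#'   default threshold.
#' @return A `ppi_fixture` bundle (file paths, truth table/graph/overlaps,
#'   bookkeeping counts).
#' @export
gen_random_ppi <- function(n_proteins, n_edges,
                           source_mix = c(PINA = 0.5, iRefIndex = 0.35,
                                          STRING = 0.3),
                           seed = 0L,
                           dir = tempfile("ppifix"),
                           decoy_fraction = 0.05,
                           score_range = c(700L, 999L)) {
  stopifnot_count(n_proteins, "n_proteins", min = 2L)
  stopifnot_count(n_edges, "n_edges", min = 1L)
  max_edges <- n_proteins * (n_proteins - 1) / 2
  if (n_edges > max_edges) {
    abort(sprintf("n_edges = %d exceeds the %d distinct pairs of %d proteins",
                  n_edges, max_edges, n_proteins),
          class = "ppipath_parameter_error")
  }
  dbs <- c("PINA", "iRefIndex", "STRING")
  if (is.null(names(source_mix)) || !all(names(source_mix) %in% dbs)) {
    abort("`source_mix` must be named with PINA/iRefIndex/STRING",
          class = "ppipath_parameter_error")
  }
  mix <- setNames(rep(0, 3L), dbs)
  mix[names(source_mix)] <- source_mix
  if (any(mix < 0 | mix > 1) || sum(mix) <= 0) {
    abort("`source_mix` probabilities must lie in [0, 1] with a positive sum",
          class = "ppipath_parameter_error")
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    acc <- sprintf("P%05d", seq_len(n_proteins))
    gene <- sprintf("GN%04d", seq_len(n_proteins))
    reviewed <- stats::runif(n_proteins) < 0.8

    all_pairs <- combn(n_proteins, 2L)
    picked <- all_pairs[, sample.int(ncol(all_pairs), n_edges), drop = FALSE]
    pairs <- canonical_pair(acc[picked[1L, ]], acc[picked[2L, ]])
    pair_keys <- paste(pairs$acc_a, pairs$acc_b, sep = "\r")

    membership <- matrix(FALSE, n_edges, 3L, dimnames = list(NULL, dbs))
    for (s in dbs) membership[, s] <- stats::runif(n_edges) < mix[[s]]
    none <- which(rowSums(membership) == 0L)
    if (length(none)) {
      fill <- sample(dbs, length(none), replace = TRUE, prob = mix)
      for (k in seq_along(none)) membership[none[[k]], fill[[k]]] <- TRUE
    }

    string_score <- rep(NA_integer_, n_edges)
    n_str <- sum(membership[, "STRING"])
    if (n_str) {
      string_score[membership[, "STRING"]] <-
        sample(seq.int(score_range[[1L]], score_range[[2L]]), n_str, replace = TRUE)
    }

    # curated PubMed support per (edge, source); duplicated lines get extras
    pmids_for <- list(PINA = vector("list", n_edges),
                      iRefIndex = vector("list", n_edges))
    curated_id <- function(i) {
      if (stats::runif(1) < 0.3) gene[[i]] else paste0("uniprotkb:", acc[[i]])
    }
    lines <- list(PINA = character(0), iRefIndex = character(0))
    for (s in c("PINA", "iRefIndex")) {
      maker <- if (s == "PINA") pina_line else iref_line
      for (e in which(membership[, s])) {
        ia <- curated_id(picked[1L, e]); ib <- curated_id(picked[2L, e])
        pm <- fake_pmids(sample.int(3L, 1L))
        lines[[s]] <- c(lines[[s]], maker(ia, ib, pm))
        if (stats::runif(1) < 0.1) {       # duplicate record, extra support
          pm2 <- fake_pmids(1L)
          lines[[s]] <- c(lines[[s]], maker(ib, ia, pm2))
          pm <- sort(unique(c(pm, pm2)))
        }
        pmids_for[[s]][[e]] <- pm
      }
    }

    string_id <- setNames(sprintf("%sENSP%011d", STRING_SPECIES_PREFIX,
                                  seq_len(n_proteins)), acc)
    string_rows <- character(0)
    for (e in which(membership[, "STRING"])) {
      string_rows <- c(string_rows,
                       paste(string_id[[pairs$acc_a[[e]]]],
                             string_id[[pairs$acc_b[[e]]]],
                             string_score[[e]]))
    }
    alias_rows <- paste(string_id, gene, "Ensemble_gene", sep = "\t")

    # decoy records: parseable but unmappable, so the mapping stage must
    # discard them without disturbing the truth network
    n_curated <- lengths(lines)
    decoys <- list(
      PINA = as.integer(round(decoy_fraction * n_curated[["PINA"]])),
      iRefIndex = as.integer(round(decoy_fraction * n_curated[["iRefIndex"]])),
      STRING = as.integer(round(decoy_fraction * length(string_rows)))
    )
    for (s in c("PINA", "iRefIndex")) {
      if (decoys[[s]] > 0L) {
        maker <- if (s == "PINA") pina_line else iref_line
        for (k in seq_len(decoys[[s]])) {
          lines[[s]] <- c(lines[[s]],
                          maker(sprintf("DECOY_%s_%d", s, k),
                                paste0("uniprotkb:", sample(acc, 1L)),
                                fake_pmids(1L)))
        }
      }
    }
    if (decoys$STRING > 0L) {
      for (k in seq_len(decoys$STRING)) {
        did <- sprintf("%sENSPDECOY%05d", STRING_SPECIES_PREFIX, k)
        alias_rows <- c(alias_rows, paste(did, sprintf("DECOYSTR%d", k),
                                          "Ensemble_gene", sep = "\t"))
        string_rows <- c(string_rows,
                         paste(did, string_id[[sample(acc, 1L)]],
                               sample(seq.int(score_range[[1L]], score_range[[2L]]), 1L)))
      }
    }

    bundle_dir <- dir
    write_lines_lf(c(PINA_HEADER, lines$PINA), file.path(bundle_dir, "pina.tsv"))
    write_lines_lf(c(IREF_HEADER, lines$iRefIndex),
                   file.path(bundle_dir, "irefindex.tsv"))
    write_lines_lf(c("protein1 protein2 combined_score", string_rows),
                   file.path(bundle_dir, "string_links.txt"))
    write_lines_lf(c("#string_protein_id\talias\tsource", alias_rows),
                   file.path(bundle_dir, "string_aliases.tsv"))
    write_fixture_mapping(acc, gene, reviewed, file.path(bundle_dir, "mapping.tsv"))

    sources_txt <- apply(membership, 1L, function(m) join_sources(dbs[m]))
    pmids_txt <- vapply(seq_len(n_edges), function(e) {
      join_pmids(c(pmids_for$PINA[[e]], pmids_for$iRefIndex[[e]]))
    }, character(1))
    truth_table <- tibble(
      acc_a = pairs$acc_a, acc_b = pairs$acc_b,
      sources = sources_txt, pmids = pmids_txt,
      string_score = string_score, cost = NA_real_
    ) |> arrange(.data$acc_a, .data$acc_b)

    present <- dbs[colSums(membership) > 0L]
    truth_overlaps <- overlaps_from_bookkeeping(
      setNames(lapply(present, function(s) membership[, s]), present),
      pair_keys
    )
    new_fixture(dir, truth_table, truth_overlaps, as.integer(seed),
                counts = list(
                  pina_lines = length(lines$PINA),
                  iref_lines = length(lines$iRefIndex),
                  string_rows = length(string_rows),
                  decoys = decoys,
                  per_source_edges = colSums(membership)
                ),
                sources_present = present)
  })
}

#' Generate a layered path-counting fixture
#'
#' Builds a layered graph from a single source to a single sink in which
#' consecutive layers are completely connected and every edge is a curated
#' (cost 1) interaction, so the number of distinct shortest source-to-sink
#' paths equals the product of the interior layer widths and the optimal
#' cost equals the number of layers minus one. Used as ground truth for
#' path enumeration.
#'
#' @param layers Integer vector of layer widths; at least 2 layers, first
#'   and last of width 1 (the source and the sink).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return A `ppi_fixture` with extras `source`, `sink`, `n_paths`,
#'   `path_cost`.
#' @export
gen_path_graph <- function(layers, seed = 0L, dir = tempfile("ppifix")) {
  layers <- as.integer(layers)
  if (length(layers) < 2L || any(layers < 1L)) {
    abort("`layers` needs >= 2 entries, each >= 1", class = "ppipath_parameter_error")
  }
  if (layers[[1L]] != 1L || layers[[length(layers)]] != 1L) {
    abort("first and last layer must have width 1 (single source and sink)",
          class = "ppipath_parameter_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    node <- function(l, i) sprintf("Q%02d%03d", l, i)
    layer_nodes <- lapply(seq_along(layers),
                          function(l) vapply(seq_len(layers[[l]]), node,
                                             character(1), l = l))
    edges <- list()
    for (l in seq_len(length(layers) - 1L)) {
      for (a in layer_nodes[[l]]) for (b in layer_nodes[[l + 1L]]) {
        edges[[length(edges) + 1L]] <- c(a, b)
      }
    }
    acc <- unlist(layer_nodes)
    pm <- write_curated_fixture(edges, acc, dir)
    truth_table <- curated_truth_table(edges, pm)
    new_fixture(dir, truth_table,
                overlaps_from_bookkeeping(
                  list(PINA = rep(TRUE, length(edges))),
                  paste(truth_table$acc_a, truth_table$acc_b, sep = "\r")),
                as.integer(seed),
                counts = list(pina_lines = length(edges)),
                sources_present = "PINA",
                extras = list(
                  source = layer_nodes[[1L]][[1L]],
                  sink = layer_nodes[[length(layers)]][[1L]],
                  n_paths = as.integer(prod(layers[-c(1L, length(layers))])),
                  path_cost = length(layers) - 1L
                ))
  })
}

#' Generate a star (hub) fixture
#'
#' One center protein interacting with `n_neighbors` leaves via curated
#' (cost 1) edges — the canonical stress case for display sampling of
#' hubs with many interactions.
#'
#' @param n_neighbors Number of leaves (>= 1).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return A `ppi_fixture` with extra `center`.
#' @export
gen_hub <- function(n_neighbors, seed = 0L, dir = tempfile("ppifix")) {
  stopifnot_count(n_neighbors, "n_neighbors")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(seed, {
    center <- "P00000"
    leaves <- sprintf("P%05d", seq_len(n_neighbors))
    edges <- lapply(leaves, function(l) c(center, l))
    pm <- write_curated_fixture(edges, c(center, leaves), dir)
    truth_table <- curated_truth_table(edges, pm)
    new_fixture(dir, truth_table,
                overlaps_from_bookkeeping(
                  list(PINA = rep(TRUE, length(edges))),
                  paste(truth_table$acc_a, truth_table$acc_b, sep = "\r")),
                as.integer(seed),
                counts = list(pina_lines = length(edges)),
                sources_present = "PINA",
                extras = list(center = center))
  })
}

# shared by the deterministic-topology generators: all-PINA edge files with
# one synthetic PubMed ID per edge, plus header-only files for the other
# dialects so bundles always expose the full file set
write_curated_fixture <- function(edges, accessions, dir) {
  pm <- lapply(edges, function(e) fake_pmids(1L))
  lines <- vapply(seq_along(edges), function(i) {
    pina_line(paste0("uniprotkb:", edges[[i]][[1L]]),
              paste0("uniprotkb:", edges[[i]][[2L]]), pm[[i]])
  }, character(1))
  write_lines_lf(c(PINA_HEADER, lines), file.path(dir, "pina.tsv"))
  write_lines_lf(IREF_HEADER, file.path(dir, "irefindex.tsv"))
  write_lines_lf("protein1 protein2 combined_score",
                 file.path(dir, "string_links.txt"))
  write_lines_lf("#string_protein_id\talias\tsource",
                 file.path(dir, "string_aliases.tsv"))
  write_fixture_mapping(accessions, paste0("GN_", accessions),
                        rep(TRUE, length(accessions)),
                        file.path(dir, "mapping.tsv"))
  pm
}

curated_truth_table <- function(edges, pm) {
  pairs <- canonical_pair(vapply(edges, `[[`, character(1), 1L),
                          vapply(edges, `[[`, character(1), 2L))
  tibble(
    acc_a = pairs$acc_a, acc_b = pairs$acc_b,
    sources = "PINA",
    pmids = vapply(pm, join_pmids, character(1)),
    string_score = NA_integer_, cost = NA_real_
  ) |> arrange(.data$acc_a, .data$acc_b)
}

#' Run the full integration pipeline over a fixture bundle
#'
#' Parses every dialect file the bundle populated, builds the mapping
#' table, canonicalizes each source, combines them, and builds the graph —
#' the same sequence a user runs on real downloads. The result should
#' reproduce the bundle's ground truth exactly.
#'
#' @param bundle A `ppi_fixture`.
#' @param score_threshold STRING threshold passed to [parse_string()].
#' @return List with `mapping`, `sets`, `table`, `overlaps`, `graph`.
#' @export
run_fixture_pipeline <- function(bundle, score_threshold = 700L) {
  stopifnot(inherits(bundle, "ppi_fixture"))
  mapping <- build_mapping(bundle$mapping_path)
  sets <- list()
  if ("PINA" %in% bundle$sources_present) {
    sets <- c(sets, list(canonicalize(parse_pina(bundle$pina_path), mapping)))
  }
  if ("iRefIndex" %in% bundle$sources_present) {
    sets <- c(sets, list(canonicalize(parse_irefindex(bundle$iref_path), mapping)))
  }
  if ("STRING" %in% bundle$sources_present) {
    sets <- c(sets, list(canonicalize(
      parse_string(bundle$string_links_path, bundle$string_alias_path,
                   score_threshold = score_threshold),
      mapping)))
  }
  combined <- combine_ppi(sets)
  list(mapping = mapping, sets = sets, table = combined$table,
       overlaps = combined$overlaps, graph = build_graph(combined$table))
}
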