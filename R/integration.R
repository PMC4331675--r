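#' Canonicalize raw interaction records against a mapping table
#'
#' Resolves both interactors of every record to primary UniProtKB
#' accessions, discards (and counts) records with any unmappable
#' interactor, stores pairs in canonical order, and merges duplicate pairs
#' within the source (union of PubMed IDs, maximum STRING score).
#'
#' @param records A tibble of raw records from one source database, as
#'   returned by the dialect parsers; all rows must share one `source_db`.
#' @param mapping A `ppi_mapping` from [build_mapping()].
#' @return A `ppi_canonical` object: the source name, a tibble of unique
#'   canonical interactions (`acc_a`, `acc_b`, `pmids` list-column,
#'   `string_score`), and the number of discarded records.
#' @export
canonicalize <- function(records, mapping) {
  stopifnot(inherits(mapping, "ppi_mapping"))
  src <- unique(records$source_db)
  if (length(src) != 1L) {
    abort("`records` must all come from a single source database",
          class = "ppipath_usage_error")
  }
  a <- resolve_protein(records$id_a, mapping)
  b <- resolve_protein(records$id_b, mapping)
  keep <- !is.na(a) & !is.na(b)
  discarded <- sum(!keep)

  pairs <- canonical_pair(a[keep], b[keep])
  recs <- tibble(
    acc_a = pairs$acc_a,
    acc_b = pairs$acc_b,
    pmids = records$pmids[keep],
    string_score = records$string_score[keep]
  )
  key <- paste(recs$acc_a, recs$acc_b, sep = "\r")
  groups <- split(seq_len(nrow(recs)), key)
  groups <- groups[order(names(groups))]
  merged <- purrr::map(groups, function(idx) {
    list(
      acc_a = recs$acc_a[[idx[[1L]]]],
      acc_b = recs$acc_b[[idx[[1L]]]],
      pmids = sort(unique(unlist(recs$pmids[idx]))),
      string_score = if (all(is.na(recs$string_score[idx]))) NA_integer_
                     else max(recs$string_score[idx], na.rm = TRUE)
    )
  })
  interactions <- tibble(
    acc_a = unname(vapply(merged, `[[`, character(1), "acc_a")),
    acc_b = unname(vapply(merged, `[[`, character(1), "acc_b")),
    pmids = unname(lapply(merged, function(m) as.integer(m$pmids))),
    string_score = unname(vapply(merged, `[[`, integer(1), "string_score"))
  )
  structure(
    list(source_db = src, interactions = interactions, discarded = discarded),
    class = "ppi_canonical"
  )
}

#' @export
print.ppi_canonical <- function(x, ...) {
  cat(sprintf("<ppi_canonical> %s: %d interactions, %d records discarded as unmappable\n",
              x$source_db, nrow(x$interactions), x$discarded))
  invisible(x)
}

item_sets <- function(set) {
  pairs <- paste(set$interactions$acc_a, set$interactions$acc_b, sep = "\r")
  proteins <- unique(c(set$interactions$acc_a, set$interactions$acc_b))
  list(proteins = proteins, pairs = pairs)
}

overlap_matrix <- function(items) {
  dbs <- names(items)
  m <- matrix(0L, length(dbs), length(dbs), dimnames = list(dbs, dbs))
  for (i in dbs) for (j in dbs) {
    m[i, j] <- length(intersect(items[[i]], items[[j]]))
  }
  m
}

distinct_counts <- function(items) {
  dbs <- names(items)
  vapply(dbs, function(d) {
    others <- unique(unlist(items[setdiff(dbs, d)]))
    sum(!(items[[d]] %in% others))
  }, integer(1))
}

#' Combine canonical interaction sets from several databases
#'
#' Merges one canonical set per source database into a single standardized
#' interaction table (one row per unordered pair; supporting sources and
#' PubMed IDs unioned; the STRING score carried over when STRING supports
#' the pair) and counts, for each database, its valid proteins and
#' interactions, the pairwise overlaps with every other database, and the
#' items distinct to it. A protein is "valid" for a database when it
#' appears in at least one of that database's kept interactions. Diagonal
#' entries of the overlap matrices hold the per-database totals. Privately
#' collected data can participate as an additional set under a user-chosen
#' source label.
#'
#' @param sets List of `ppi_canonical` objects with pairwise-distinct
#'   source labels.
#' @return A list with components `table` (the standardized tibble,
#'   [write_standard()]-ready) and `overlaps` (a `ppi_overlap`).
#' @export
combine_ppi <- function(sets) {
  if (length(sets) < 1L) {
    abort("need at least one canonical set", class = "ppipath_usage_error")
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "ppi_canonical")))
  dbs <- vapply(sets, `[[`, character(1), "source_db")
  if (anyDuplicated(dbs)) {
    abort("two sets share a source database label", class = "ppipath_usage_error")
  }
  ord <- order(dbs, method = "radix")
  sets <- sets[ord]
  dbs <- dbs[ord]
  names(sets) <- dbs

  rows <- purrr::imap(sets, function(s, db) {
    mutate(s$interactions, source_db = db)
  })
  all_rows <- bind_rows(rows)
  key <- paste(all_rows$acc_a, all_rows$acc_b, sep = "\r")
  groups <- split(seq_len(nrow(all_rows)), key)
  groups <- groups[order(names(groups))]
  merged <- purrr::map(groups, function(idx) {
    sc <- all_rows$string_score[idx]
    list(
      acc_a = all_rows$acc_a[[idx[[1L]]]],
      acc_b = all_rows$acc_b[[idx[[1L]]]],
      sources = join_sources(all_rows$source_db[idx]),
      pmids = join_pmids(unlist(all_rows$pmids[idx])),
      string_score = if (all(is.na(sc))) NA_integer_ else max(sc, na.rm = TRUE)
    )
  })
  table <- tibble(
    acc_a = unname(vapply(merged, `[[`, character(1), "acc_a")),
    acc_b = unname(vapply(merged, `[[`, character(1), "acc_b")),
    sources = unname(vapply(merged, `[[`, character(1), "sources")),
    pmids = unname(vapply(merged, `[[`, character(1), "pmids")),
    string_score = unname(vapply(merged, `[[`, integer(1), "string_score")),
    cost = rep(NA_real_, length(merged))
  )

  items <- lapply(sets, item_sets)
  protein_items <- lapply(items, `[[`, "proteins")
  pair_items <- lapply(items, `[[`, "pairs")
  overlaps <- structure(
    list(
      protein_counts = overlap_matrix(protein_items),
      interaction_counts = overlap_matrix(pair_items),
      distinct_proteins = distinct_counts(protein_items),
      distinct_interactions = distinct_counts(pair_items)
    ),
    class = "ppi_overlap"
  )
  list(table = table, overlaps = overlaps)
}

#' @export
print.ppi_overlap <- function(x, ...) {
  show <- function(m, d, what) {
    cat(sprintf("Overlapping and distinct %s per database:\n", what))
    out <- cbind(as.data.frame(m), distinct = d)
    print(out)
  }
  show(x$protein_counts, x$distinct_proteins, "proteins")
  cat("\n")
  show(x$interaction_counts, x$distinct_interactions, "interactions")
  invisible(x)
}

#' Rebuild a canonical set from rows of a standardized table
#'
#' Inverse convenience for pipelines that persist per-source standardized
#' TSVs: extracts the records a given source supports so several tables
#' can be re-[combine_ppi()]d.
#'
#' @param table A standardized interaction tibble.
#' @param source_db The source label to extract.
#' @return A `ppi_canonical`.
#' @export
canonical_from_table <- function(table, source_db) {
  validate_standard_table(table)
  hit <- purrr::map_lgl(table$sources, function(s) source_db %in% split_sources(s))
  sub <- table[hit, ]
  structure(
    list(
      source_db = source_db,
      interactions = tibble(
        acc_a = sub$acc_a,
        acc_b = sub$acc_b,
        pmids = lapply(sub$pmids, split_pmids),
        string_score = if (source_db == "STRING") sub$string_score
                       else rep(NA_integer_, nrow(sub))
      ),
      discarded = 0L
    ),
    class = "ppi_canonical"
  )
}
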