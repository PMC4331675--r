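#' Parsers for interaction-database download dialects
#'
#' Bulk PPI downloads come in several tab-delimited dialects. These readers
#' extract, for every usable line, the two interactor identifiers, the
#' supporting PubMed IDs (curated sources) or the combined confidence score
#' (STRING), and tag each record with its source database. Identifier
#' prefixes such as `uniprotkb:` are stripped; unknown prefixes are kept
#' verbatim for the mapping stage to resolve. Malformed lines are skipped
#' and counted, never fatal: bulk downloads are dirty.
#'
#' Column discovery is header-first: interactor columns default to the first
#' two columns, and the PubMed column is located by a header name matching
#' `pubmed`/`pmid`/`publication` (case-insensitive), falling back to a
#' positional default (`pmid_col`) when no header matches.
#'
#' @param path Path to a tab-delimited interaction file with a header line.
#' @param pmid_col Positional fallback for the PubMed-ID column when no
#'   header name matches; defaults to the classic column positions of each
#'   dialect (9 for PINA-style MITAB, 7 for iRefIndex-style).
#' @return A tibble of raw records with columns `id_a`, `id_b`, `source_db`,
#'   `pmids` (list-column of integer vectors) and `string_score` (integer,
#'   `NA` for curated sources). The number of skipped lines is attached as
#'   attribute `n_skipped` (and, for [parse_string()], the number of rows
#'   dropped for lack of an alias as `n_unaliased`).
#' @name dialect-parsers
NULL

KNOWN_ID_PREFIXES <- c("uniprotkb:", "refseq:", "entrezgene/locuslink:")

strip_id_prefix <- function(x) {
  x <- trimws(x)
  for (p in KNOWN_ID_PREFIXES) {
    hit <- startsWith(tolower(x), p)
    x[hit] <- substr(x[hit], nchar(p) + 1L, nchar(x[hit]))
  }
  x
}

# "pubmed:123|pubmed:456|MI:0000(x)" -> c(123L, 456L)
extract_pmids <- function(field) {
  if (is.na(field) || !nzchar(field)) return(integer(0))
  tokens <- strsplit(field, "|", fixed = TRUE)[[1]]
  hits <- grepl("^\\s*pubmed:\\s*\\d+\\s*$", tokens, ignore.case = TRUE)
  ids <- sub("^\\s*pubmed:\\s*(\\d+)\\s*$", "\\1", tokens[hits], ignore.case = TRUE)
  sort(unique(as.integer(ids)))
}

find_pmid_col <- function(header, fallback) {
  hit <- grep("pub(lication|med)|pmid", header, ignore.case = TRUE)
  if (length(hit) >= 1L) hit[[1L]] else fallback
}

parse_mitab_like <- function(path, source_db, pmid_col) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read interaction file: %s", path), class = "ppipath_io_error")
  }
  lines <- readr::read_lines(path)
  if (length(lines) < 1L) {
    abort(sprintf("%s: empty file (no header)", path), class = "ppipath_format_error")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  pmid_col <- find_pmid_col(header, pmid_col)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]

  records <- vector("list", length(body))
  n_skipped <- 0L
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) { n_skipped <- n_skipped + 1L; next }
    id_a <- strip_id_prefix(fields[[1L]])
    id_b <- strip_id_prefix(fields[[2L]])
    if (!nzchar(id_a) || !nzchar(id_b) || id_a == "-" || id_b == "-") {
      n_skipped <- n_skipped + 1L
      next
    }
    pmid_field <- if (length(fields) >= pmid_col) fields[[pmid_col]] else NA_character_
    records[[i]] <- list(id_a = id_a, id_b = id_b, pmids = extract_pmids(pmid_field))
  }
  records <- records[!vapply(records, is.null, logical(1))]
  if (length(records) == 0L) {
    abort(sprintf("%s: no parseable interaction lines", path),
          class = "ppipath_format_error")
  }
  out <- tibble(
    id_a = vapply(records, `[[`, character(1), "id_a"),
    id_b = vapply(records, `[[`, character(1), "id_b"),
    source_db = source_db,
    pmids = lapply(records, `[[`, "pmids"),
    string_score = NA_integer_
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @rdname dialect-parsers
#' @export
parse_pina <- function(path, pmid_col = 9L) {
  parse_mitab_like(path, "PINA", pmid_col)
}

#' @rdname dialect-parsers
#' @export
parse_irefindex <- function(path, pmid_col = 7L) {
  parse_mitab_like(path, "iRefIndex", pmid_col)
}

#' @rdname dialect-parsers
#' @param links_path STRING links file (whitespace-delimited; header
#'   `protein1 protein2 combined_score`).
#' @param alias_path STRING alias file translating internal IDs
#'   (`9606.ENSP...`) to external names; tab-delimited with the STRING ID in
#'   column 1 and the alias in column 2, `#`-prefixed header allowed.
#' @param score_threshold Minimum combined score (0-999) a row must reach to
#'   be kept; defaults to 700, the conventional high-confidence cutoff.
#' @export
parse_string <- function(links_path, alias_path, score_threshold = 700L) {
  if (!file.exists(links_path)) {
    abort(sprintf("cannot read STRING links file: %s", links_path),
          class = "ppipath_io_error")
  }
  if (!file.exists(alias_path)) {
    abort(sprintf("cannot read STRING alias file: %s", alias_path),
          class = "ppipath_io_error")
  }
  if (!is.numeric(score_threshold) || length(score_threshold) != 1L ||
      is.na(score_threshold) || score_threshold < 0 || score_threshold > 999) {
    abort("`score_threshold` must be a single number in [0, 999]",
          class = "ppipath_parameter_error")
  }

  alias_lines <- readr::read_lines(alias_path)
  alias_lines <- alias_lines[nzchar(trimws(alias_lines)) & !startsWith(alias_lines, "#")]
  alias_fields <- strsplit(alias_lines, "\t", fixed = TRUE)
  ok <- lengths(alias_fields) >= 2L
  alias_map <- new.env(parent = emptyenv())
  for (f in alias_fields[ok]) {
    if (!exists(f[[1L]], envir = alias_map, inherits = FALSE)) {
      assign(f[[1L]], f[[2L]], envir = alias_map)
    }
  }

  lines <- readr::read_lines(links_path)
  if (length(lines) < 1L) {
    abort(sprintf("%s: empty file (no header)", links_path),
          class = "ppipath_format_error")
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]

  n_skipped <- 0L
  n_unaliased <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(fields) < 3L) { n_skipped <- n_skipped + 1L; next }
    score <- suppressWarnings(as.integer(fields[[3L]]))
    if (is.na(score)) { n_skipped <- n_skipped + 1L; next }
    if (score < score_threshold) next
    a <- mget(fields[[1L]], envir = alias_map, ifnotfound = NA_character_)[[1L]]
    b <- mget(fields[[2L]], envir = alias_map, ifnotfound = NA_character_)[[1L]]
    if (is.na(a) || is.na(b)) { n_unaliased <- n_unaliased + 1L; next }
    recs[[i]] <- list(id_a = a, id_b = b, score = score)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- tibble(
    id_a = vapply(recs, `[[`, character(1), "id_a"),
    id_b = vapply(recs, `[[`, character(1), "id_b"),
    source_db = rep("STRING", length(recs)),
    pmids = rep(list(integer(0)), length(recs)),
    string_score = vapply(recs, function(r) as.integer(r$score), integer(1))
  )
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_unaliased") <- n_unaliased
  out
}

STANDARD_HEADER <- c("accA", "accB", "sources", "pmids", "string_score", "cost")

validate_standard_table <- function(tbl, context = "standard table") {
  needed <- c("acc_a", "acc_b", "sources", "pmids", "string_score", "cost")
  if (!all(needed %in% names(tbl))) {
    abort(sprintf("%s: missing columns %s", context,
                  paste(setdiff(needed, names(tbl)), collapse = ", ")),
          class = "ppipath_format_error")
  }
  bad <- which(tbl$acc_b < tbl$acc_a)
  if (length(bad)) {
    abort(sprintf("%s: pair not in canonical order at row %d (%s, %s)",
                  context, bad[[1L]], tbl$acc_a[[bad[[1L]]]], tbl$acc_b[[bad[[1L]]]]),
          class = "ppipath_format_error")
  }
  key <- paste(tbl$acc_a, tbl$acc_b, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(sprintf("%s: duplicate pair (%s, %s)", context,
                  tbl$acc_a[[dup[[1L]]]], tbl$acc_b[[dup[[1L]]]]),
          class = "ppipath_format_error")
  }
  if (any(!is.na(tbl$cost) & tbl$cost < 1)) {
    abort(sprintf("%s: cost overrides must be >= 1", context),
          class = "ppipath_format_error")
  }
  invisible(tbl)
}

#' Read and write the standardized interaction table
#'
#' The standardized format is the common ground all source dialects are
#' converted into: one row per unordered accession pair, with the supporting
#' databases, the union of PubMed IDs, the STRING combined score when
#' present, and an optional user-assigned cost override (>= 1). It is a
#' plain UTF-8 TSV with Unix newlines and columns
#' `accA, accB, sources, pmids, string_score, cost`, so users can edit edge
#' costs in any spreadsheet or text editor before path search.
#'
#' `read_standard(write_standard(tbl, path))` is an exact identity,
#' including cost overrides.
#'
#' @param path File path.
#' @param table A standardized interaction tibble with columns `acc_a`,
#'   `acc_b` (canonically ordered pair), `sources` (`;`-joined, sorted),
#'   `pmids` (`;`-joined, ascending), `string_score` (integer or `NA`),
#'   `cost` (numeric override >= 1, or `NA` to use the default cost model).
#' @return `read_standard()` returns the tibble; `write_standard()`
#'   invisibly returns `path`.
#' @export
read_standard <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read standard table: %s", path), class = "ppipath_io_error")
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      accA = readr::col_character(),
      accB = readr::col_character(),
      sources = readr::col_character(),
      pmids = readr::col_character(),
      string_score = readr::col_integer(),
      cost = readr::col_double()
    ),
    na = "",
    progress = FALSE
  )
  if (!identical(names(raw), STANDARD_HEADER)) {
    abort(sprintf("%s: expected columns %s", path,
                  paste(STANDARD_HEADER, collapse = ", ")),
          class = "ppipath_format_error")
  }
  tbl <- tibble(
    acc_a = raw$accA,
    acc_b = raw$accB,
    sources = ifelse(is.na(raw$sources), "", raw$sources),
    pmids = ifelse(is.na(raw$pmids), "", raw$pmids),
    string_score = raw$string_score,
    cost = raw$cost
  )
  validate_standard_table(tbl, context = path)
  tbl
}

#' @rdname read_standard
#' @export
write_standard <- function(table, path) {
  validate_standard_table(table)
  fmt_num <- function(x) {
    ifelse(is.na(x), "", vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, trim = TRUE, scientific = FALSE)
    }, character(1)))
  }
  lines <- c(
    paste(STANDARD_HEADER, collapse = "\t"),
    paste(table$acc_a, table$acc_b, table$sources, table$pmids,
          ifelse(is.na(table$string_score), "", as.character(table$string_score)),
          fmt_num(table$cost),
          sep = "\t")
  )
  write_lines_lf(lines, path)
}
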