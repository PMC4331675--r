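#' Build a protein-identifier mapping table
#'
#' PPI downloads refer to the same protein by gene names, synonyms, or
#' current and superseded accessions. To deduplicate interactions across
#' sources, every identifier is canonicalized to a primary UniProtKB
#' accession. The mapping input is a 5-column TSV:
#' `accession, reviewed, gene_name, synonyms, secondary_accessions`
#' (the last two `;`-joined, possibly empty; `reviewed` is `yes`/`no`,
#' distinguishing Swiss-Prot from TrEMBL entries).
#'
#' Name lookup is case-insensitive (gene symbols are case-ambiguous across
#' sources). When two entries claim the same name, the reviewed
#' (Swiss-Prot) entry wins; remaining ties break lexicographically by
#' accession, so the table is deterministic regardless of input row order.
#' Every primary accession always resolves to itself.
#'
#' @param mapping_input Path to the 5-column mapping TSV.
#' @return A `ppi_mapping` object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\treviewed\tgene_name\tsynonyms\tsecondary_accessions",
#'              "P04637\tyes\tTP53\tp53;LFS1\tQ15086"), tf)
#' m <- build_mapping(tf)
#' resolve_protein(c("tp53", "LFS1", "Q15086", "NOSUCHGENE"), m)
#' @export
build_mapping <- function(mapping_input) {
  if (!file.exists(mapping_input)) {
    abort(sprintf("cannot read mapping file: %s", mapping_input),
          class = "ppipath_io_error")
  }
  raw <- readr::read_tsv(
    mapping_input,
    col_types = readr::cols(.default = readr::col_character()),
    na = "",
    progress = FALSE
  )
  needed <- c("accession", "reviewed", "gene_name", "synonyms", "secondary_accessions")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("%s: expected columns %s", mapping_input,
                  paste(needed, collapse = ", ")),
          class = "ppipath_format_error")
  }
  dup <- raw$accession[duplicated(raw$accession)]
  if (length(dup)) {
    abort(sprintf("%s: duplicate primary accession row(s): %s", mapping_input,
                  paste(unique(dup), collapse = ", ")),
          class = "ppipath_format_error")
  }

  raw <- arrange(raw, .data$accession)
  reviewed <- setNames(tolower(raw$reviewed) %in% c("yes", "true", "reviewed", "1"),
                       raw$accession)
  display <- setNames(ifelse(is.na(raw$gene_name) | !nzchar(raw$gene_name),
                             raw$accession, raw$gene_name),
                      raw$accession)

  # candidate (name, accession) claims; precedence: unreviewed < reviewed,
  # then larger accession < smaller accession, applied by overwrite order
  claims <- purrr::pmap(raw, function(accession, reviewed, gene_name,
                                      synonyms, secondary_accessions, ...) {
    names <- c(accession, gene_name,
               if (!is.na(synonyms)) strsplit(synonyms, ";", fixed = TRUE)[[1L]],
               if (!is.na(secondary_accessions))
                 strsplit(secondary_accessions, ";", fixed = TRUE)[[1L]])
    names <- trimws(names[!is.na(names)])
    names <- names[nzchar(names)]
    tibble(key = tolower(names), accession = accession)
  })
  claims <- bind_rows(claims)
  claims$reviewed <- reviewed[claims$accession]
  # winner per key: reviewed first, then lexicographically smallest accession;
  # a key that IS a primary accession always resolves to that accession
  claims <- arrange(claims, .data$key, dplyr::desc(.data$reviewed), .data$accession)
  winners <- claims[!duplicated(claims$key), ]
  self_keys <- tolower(raw$accession)
  lookup <- setNames(winners$accession, winners$key)
  lookup[self_keys] <- raw$accession

  structure(
    list(lookup = lookup, display = display, reviewed = reviewed),
    class = "ppi_mapping"
  )
}

#' @export
print.ppi_mapping <- function(x, ...) {
  cat(sprintf("<ppi_mapping> %d primary accessions (%d reviewed), %d resolvable names\n",
              length(x$display), sum(x$reviewed), length(x$lookup)))
  invisible(x)
}

#' Resolve names to primary accessions
#'
#' Case-insensitive lookup of gene names, synonyms, or (secondary)
#' accessions against a [build_mapping()] table. A failed lookup returns
#' `NA` rather than throwing, so callers can implement the discard rule for
#' unmappable proteins. Resolution is idempotent: resolving an already
#' primary accession returns it unchanged.
#'
#' @param query Character vector of names or accessions.
#' @param mapping A `ppi_mapping`.
#' @return Character vector of primary accessions, `NA` where unmappable.
#' @export
resolve_protein <- function(query, mapping) {
  stopifnot(inherits(mapping, "ppi_mapping"))
  out <- unname(mapping$lookup[tolower(trimws(as.character(query)))])
  out
}

#' Preferred display name for an accession
#'
#' @param accession Character vector of primary accessions.
#' @param mapping A `ppi_mapping`.
#' @return The preferred gene names (the accession itself when unknown).
#' @export
display_name <- function(accession, mapping) {
  stopifnot(inherits(mapping, "ppi_mapping"))
  out <- unname(mapping$display[accession])
  ifelse(is.na(out), accession, out)
}

#' Convert a two-column idmapping-style file to the 5-column mapping TSV
#'
#' Convenience reader for flat `name<TAB>accession` dumps: every name
#' becomes a synonym of its accession; accessions are marked unreviewed
#' because a two-column dump carries no review status.
#'
#' @param path Two-column TSV (`name`, `accession`), no header.
#' @param out Destination for the 5-column mapping TSV.
#' @return Invisibly, `out`.
#' @export
convert_idmapping <- function(path, out) {
  raw <- readr::read_tsv(path, col_names = c("name", "accession"),
                         col_types = "cc", progress = FALSE)
  per_acc <- raw |>
    group_by(.data$accession) |>
    summarise(synonyms = paste(sort(unique(.data$name)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$accession)
  lines <- c(
    "accession\treviewed\tgene_name\tsynonyms\tsecondary_accessions",
    paste(per_acc$accession, "no", "", per_acc$synonyms, "", sep = "\t")
  )
  write_lines_lf(lines, out)
}

#' Write a 5-column mapping TSV
#'
#' @param entries Tibble with columns `accession`, `reviewed` (logical),
#'   `gene_name`, `synonyms` (character, `;`-joined), `secondary_accessions`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_mapping <- function(entries, path) {
  lines <- c(
    "accession\treviewed\tgene_name\tsynonyms\tsecondary_accessions",
    paste(entries$accession,
          ifelse(entries$reviewed, "yes", "no"),
          entries$gene_name,
          entries$synonyms,
          entries$secondary_accessions,
          sep = "\t")
  )
  write_lines_lf(lines, path)
}
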