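#' Canonical ordering for an unordered protein pair
#'
#' Interactions are unordered; everywhere in the package a pair is stored
#' with the lexicographically smaller accession first so that (A, B) and
#' (B, A) collapse to one record. Self-pairs (homodimers) are allowed.
#'
#' @param a,b Character vectors of accessions (recycled together).
#' @return A tibble with columns `acc_a` and `acc_b`, `acc_a <= acc_b`.
#' @examples
#' canonical_pair(c("Q13625", "P04637"), c("P04637", "Q13625"))
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- b < a
  tibble(
    acc_a = ifelse(swap, b, a),
    acc_b = ifelse(swap, a, b)
  )
}

# ";"-join a set of integer PubMed IDs in ascending order ("" if none)
join_pmids <- function(pmids) {
  pmids <- sort(unique(as.integer(pmids)))
  paste(pmids, collapse = ";")
}

# inverse of join_pmids
split_pmids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  sort(unique(as.integer(strsplit(x, ";", fixed = TRUE)[[1]])))
}

join_sources <- function(sources) {
  paste(sort(unique(as.character(sources)), method = "radix"), collapse = ";")
}

split_sources <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(strsplit(x, ";", fixed = TRUE)[[1]]), method = "radix")
}

# Signal a lookup miss (unknown protein / unresolvable name) as a classed
# condition so callers can catch it and apply the discard rule themselves.
miss <- function(message, ...) {
  abort(message, class = "ppipath_miss", ...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "ppipath_parameter_error")
  }
}

# Write lines with Unix newlines regardless of platform
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
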