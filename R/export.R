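#' Default UniProt entry hyperlink template
#'
#' `%s` is replaced by the accession. Node links in rendered pages point
#' here so evidence can be checked at the source.
#' @export
UNIPROT_LINK_TEMPLATE <- "https://www.uniprot.org/uniprotkb/%s/entry"

summarise_evidence <- function(sources, pmids, string_score) {
  bits <- sources
  if (nzchar(pmids)) bits <- paste0(bits, "; PubMed ", gsub(";", ",", pmids))
  if (!is.na(string_score)) bits <- paste0(bits, "; STRING score ", string_score)
  bits
}

new_view_document <- function(nodes, links, evidence, paths, metadata) {
  structure(
    list(nodes = nodes, links = links, evidence = evidence,
         paths = paths, metadata = metadata),
    class = "ppi_view_document"
  )
}

#' Convert a view or path set into a renderable document
#'
#' A view document is the complete, renderer-independent description of a
#' network page: styled nodes with UniProt hyperlinks, the links to draw
#' (the display sample when one was taken), the full evidence table (one
#' row per interaction of the originating view, never sampled), and — for
#' path results — the list of individual shortest paths so each can be
#' highlighted when selected.
#'
#' @param x A `ppi_view` or `ppi_path_set`.
#' @param mapping Optional `ppi_mapping` used for display labels.
#' @param link_template `sprintf` template for node hyperlinks.
#' @param ... Unused.
#' @return A `ppi_view_document`.
#' @export
as_view_document <- function(x, mapping = NULL,
                             link_template = UNIPROT_LINK_TEMPLATE, ...) {
  UseMethod("as_view_document")
}

doc_nodes <- function(ids, style, mapping, link_template) {
  labels <- if (is.null(mapping)) ids else display_name(ids, mapping)
  tibble(
    id = ids,
    label = labels,
    color_class = style$color_class[match(ids, style$node)],
    size_class = style$size_class[match(ids, style$node)],
    href = sprintf(link_template, ids)
  )
}

doc_links <- function(edges) {
  tibble(
    source = edges$acc_a,
    target = edges$acc_b,
    evidence = purrr::pmap_chr(
      list(edges$sources, edges$pmids, edges$string_score), summarise_evidence),
    directed = rep(FALSE, nrow(edges)),
    style = rep("", nrow(edges))
  )
}

#' @rdname as_view_document
#' @export
as_view_document.ppi_view <- function(x, mapping = NULL,
                                      link_template = UNIPROT_LINK_TEMPLATE, ...) {
  ids <- x$style$node
  new_view_document(
    nodes = doc_nodes(ids, x$style, mapping, link_template),
    links = doc_links(x$display_edges),
    evidence = x$edges,
    paths = x$paths,
    metadata = list(
      type = "view",
      sampled = x$sampled,
      n_edges_total = nrow(x$edges),
      unreachable = isTRUE(x$unreachable)
    )
  )
}

#' @rdname as_view_document
#' @export
as_view_document.ppi_path_set <- function(x, mapping = NULL,
                                          link_template = UNIPROT_LINK_TEMPLATE,
                                          ...) {
  ids <- sort(unique(unlist(x$paths)))
  endpoints <- intersect(c(x$source, x$target), ids)
  style <- tibble(
    node = ids,
    role = ifelse(ids %in% endpoints, "main", "path"),
    color_class = ifelse(ids %in% endpoints, "main", "path"),
    size_class = ifelse(ids %in% endpoints, "large", "small")
  )
  ev <- x$evidence %||% empty_view_edges()
  new_view_document(
    nodes = doc_nodes(ids, style, mapping, link_template),
    links = doc_links(ev),
    evidence = ev,
    paths = x$paths,
    metadata = list(
      type = "paths",
      source = x$source, target = x$target,
      total_cost = x$total_cost, by_step = x$by_step,
      truncated = x$truncated, unreachable = x$unreachable
    )
  )
}

#' @export
print.ppi_view_document <- function(x, ...) {
  cat(sprintf("<ppi_view_document> %d node(s), %d link(s), %d evidence row(s)%s\n",
              nrow(x$nodes), nrow(x$links), nrow(x$evidence),
              if (!is.null(x$paths)) sprintf(", %d path(s)", length(x$paths)) else ""))
  invisible(x)
}

doc_to_json <- function(doc) {
  payload <- list(
    nodes = doc$nodes,
    links = doc$links,
    evidence = mutate(doc$evidence,
                      string_score = as.integer(.data$string_score)),
    paths = doc$paths %||% list(),
    metadata = doc$metadata
  )
  jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                   na = "null", digits = NA, pretty = FALSE)
}

json_to_doc <- function(txt) {
  p <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  as_df <- function(x, template) {
    if (is.null(x) || length(x) == 0L) return(template)
    out <- as_tibble(x)
    for (nm in names(template)) {
      if (!nm %in% names(out)) out[[nm]] <- template[[nm]][0][seq_len(nrow(out))]
      mode_fun <- switch(class(template[[nm]])[[1]],
                         integer = as.integer, numeric = as.numeric,
                         logical = as.logical, as.character)
      out[[nm]] <- mode_fun(out[[nm]])
    }
    out[names(template)]
  }
  nodes_t <- tibble(id = character(0), label = character(0),
                    color_class = character(0), size_class = character(0),
                    href = character(0))
  links_t <- tibble(source = character(0), target = character(0),
                    evidence = character(0), directed = logical(0),
                    style = character(0))
  paths <- p$paths
  if (is.null(paths)) paths <- list()
  if (is.matrix(paths)) paths <- lapply(seq_len(nrow(paths)), function(i) paths[i, ])
  if (is.character(paths)) paths <- list(paths)
  new_view_document(
    nodes = as_df(p$nodes, nodes_t),
    links = as_df(p$links, links_t),
    evidence = as_df(p$evidence, empty_view_edges()),
    paths = if (length(paths)) lapply(paths, as.character) else
      if (identical(p$metadata$type, "paths")) list() else NULL,
    metadata = as.list(p$metadata)
  )
}

#' Persist a view document as JSON
#'
#' Open sidecar layout for view documents so rendered pages and their data
#' can be regenerated or post-processed by other tools.
#'
#' @param doc A `ppi_view_document`.
#' @param path Destination (`write_`) or source (`read_`) file.
#' @return `read_view_document()` returns the document; the writer
#'   invisibly returns `path`.
#' @export
write_view_document <- function(doc, path) {
  stopifnot(inherits(doc, "ppi_view_document"))
  write_lines_lf(as.character(doc_to_json(doc)), path)
}

#' @rdname write_view_document
#' @export
read_view_document <- function(path) {
  json_to_doc(paste(readr::read_lines(path), collapse = "\n"))
}
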