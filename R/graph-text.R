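GRAPH_TEXT_TAG <- "PPIGT1"

gt_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("|", "%7C", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub(":", "%3A", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

gt_unescape <- function(x) {
  x <- gsub("%7C", "|", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3A", ":", x, fixed = TRUE)
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Reversible one-line text encoding of a network view
#'
#' Serializes the graph portion of a view document — nodes with labels and
#' style classes, edges with directedness flags and edge styles — into a
#' single line of printable text that can be pasted into an email or
#' messenger and parsed back into an identical editable graph. The payload
#' is versioned (`PPIGT1|...`) so future dialects can coexist; reserved
#' characters inside fields are percent-escaped.
#'
#' `parse_graph_text(serialize_graph_text(doc))` reproduces the nodes,
#' edges, directedness flags and style classes of `doc` exactly.
#'
#' @param doc A `ppi_view_document`.
#' @return A single string of class `ppi_graph_text`.
#' @export
serialize_graph_text <- function(doc) {
  stopifnot(inherits(doc, "ppi_view_document"))
  n <- doc$nodes
  node_part <- paste(
    paste(gt_escape(n$id), gt_escape(n$label),
          gt_escape(n$color_class), gt_escape(n$size_class), sep = ":"),
    collapse = ";"
  )
  l <- doc$links
  edge_part <- paste(
    paste(gt_escape(l$source), gt_escape(l$target),
          ifelse(l$directed, "1", "0"), gt_escape(l$style), sep = ":"),
    collapse = ";"
  )
  structure(paste0(GRAPH_TEXT_TAG, "|N:", node_part, "|E:", edge_part),
            class = c("ppi_graph_text", "character"))
}

gt_error <- function(msg, pos) {
  abort(sprintf("malformed graph text at character %d: %s", pos, msg),
        class = "ppipath_parse_error")
}

split_fields <- function(segment, n_fields, offset, what) {
  if (!nzchar(segment)) return(NULL)
  items <- strsplit(segment, ";", fixed = TRUE)[[1L]]
  pos <- offset
  out <- vector("list", length(items))
  for (i in seq_along(items)) {
    fields <- strsplit(items[[i]], ":", fixed = TRUE)[[1L]]
    # a trailing empty field is dropped by strsplit; restore it
    if (length(fields) == n_fields - 1L && endsWith(items[[i]], ":")) {
      fields <- c(fields, "")
    }
    if (length(fields) != n_fields) {
      gt_error(sprintf("%s entry needs %d ':'-separated fields, found %d",
                       what, n_fields, length(fields)), pos)
    }
    out[[i]] <- gt_unescape(fields)
    pos <- pos + nchar(items[[i]]) + 1L
  }
  out
}

#' @rdname serialize_graph_text
#' @param text A graph-text payload string.
#' @param link_template `sprintf` template used to rebuild node hyperlinks.
#' @export
parse_graph_text <- function(text, link_template = UNIPROT_LINK_TEMPLATE) {
  text <- as.character(text)
  if (length(text) != 1L || is.na(text)) {
    abort("graph text must be a single string", class = "ppipath_parse_error")
  }
  prefix <- paste0(GRAPH_TEXT_TAG, "|N:")
  if (!startsWith(text, prefix)) {
    gt_error(sprintf("expected payload to start with '%s'", prefix), 1L)
  }
  rest <- substr(text, nchar(prefix) + 1L, nchar(text))
  e_at <- regexpr("|E:", rest, fixed = TRUE)
  if (e_at < 0L) gt_error("missing '|E:' edge section", nchar(prefix) + 1L)
  node_seg <- substr(rest, 1L, e_at - 1L)
  edge_seg <- substr(rest, e_at + 3L, nchar(rest))
  if (grepl("|", edge_seg, fixed = TRUE)) {
    gt_error("unexpected '|' after the edge section",
             nchar(prefix) + e_at + 3L + regexpr("|", edge_seg, fixed = TRUE) - 1L)
  }

  nodes <- split_fields(node_seg, 4L, nchar(prefix) + 1L, "node")
  edges <- split_fields(edge_seg, 4L, nchar(prefix) + nchar(node_seg) + 4L, "edge")

  nodes_tbl <- if (is.null(nodes)) {
    tibble(id = character(0), label = character(0), color_class = character(0),
           size_class = character(0), href = character(0))
  } else {
    tibble(
      id = vapply(nodes, `[[`, character(1), 1L),
      label = vapply(nodes, `[[`, character(1), 2L),
      color_class = vapply(nodes, `[[`, character(1), 3L),
      size_class = vapply(nodes, `[[`, character(1), 4L),
      href = sprintf(link_template, vapply(nodes, `[[`, character(1), 1L))
    )
  }
  links_tbl <- if (is.null(edges)) {
    tibble(source = character(0), target = character(0), evidence = character(0),
           directed = logical(0), style = character(0))
  } else {
    flags <- vapply(edges, `[[`, character(1), 3L)
    if (!all(flags %in% c("0", "1"))) {
      gt_error("edge directedness flag must be 0 or 1",
               nchar(prefix) + nchar(node_seg) + 4L)
    }
    tibble(
      source = vapply(edges, `[[`, character(1), 1L),
      target = vapply(edges, `[[`, character(1), 2L),
      evidence = rep("", length(edges)),
      directed = flags == "1",
      style = vapply(edges, `[[`, character(1), 4L)
    )
  }
  unknown <- setdiff(unique(c(links_tbl$source, links_tbl$target)), nodes_tbl$id)
  if (length(unknown)) {
    gt_error(sprintf("edge references undeclared node '%s'", unknown[[1L]]),
             nchar(prefix) + nchar(node_seg) + 4L)
  }
  new_view_document(
    nodes = nodes_tbl,
    links = links_tbl,
    evidence = empty_view_edges(),
    paths = NULL,
    metadata = list(type = "graph_text", format = GRAPH_TEXT_TAG)
  )
}

#' @export
print.ppi_graph_text <- function(x, ...) {
  s <- unclass(x)
  cat(sprintf("<ppi_graph_text> %d characters\n", nchar(s)))
  cat(if (nchar(s) > 70) paste0(substr(s, 1, 67), "...") else s, "\n")
  invisible(x)
}
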