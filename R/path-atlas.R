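#' Export a single-source screening result as browsable documents
#'
#' Shards a [single_source()] atlas into one view document per target
#' (JSON sidecar plus rendered HTML page) and writes an index document
#' listing every reachable target with its optimal cost, so the whole
#' screen can be hosted on a web server or cloud drive and browsed
#' without launching R.
#'
#' @param atlas A `ppi_path_atlas`.
#' @param dir Output directory (created if needed).
#' @param mapping Optional `ppi_mapping` for display labels.
#' @param html Also render one HTML page per target (default `TRUE`).
#' @return Invisibly, the index file path.
#' @export
write_path_atlas <- function(atlas, dir, mapping = NULL, html = TRUE) {
  stopifnot(inherits(atlas, "ppi_path_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src <- attr(atlas, "source")
  index <- tibble(
    target = names(atlas),
    total_cost = vapply(atlas, `[[`, numeric(1), "total_cost"),
    n_paths = vapply(atlas, function(p) length(p$paths), integer(1)),
    truncated = vapply(atlas, `[[`, logical(1), "truncated"),
    document = paste0("path_", names(atlas), ".json")
  )
  for (tgt in names(atlas)) {
    doc <- as_view_document(atlas[[tgt]], mapping = mapping)
    write_view_document(doc, file.path(dir, paste0("path_", tgt, ".json")))
    if (html) render_html(doc, file.path(dir, paste0("path_", tgt, ".html")))
  }
  idx_path <- file.path(dir, "index.json")
  write_lines_lf(as.character(jsonlite::toJSON(
    list(source = src, by_step = attr(atlas, "by_step"), targets = index),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)), idx_path)
  invisible(idx_path)
}
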