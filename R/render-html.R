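html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# minimal self-contained force-directed renderer; inlined so pages work
# from a local file system or a cloud drive with no server and no CDN
FORCE_LAYOUT_JS <- "
(function () {
  var data = JSON.parse(document.getElementById('ppipath-data').textContent);
  var svg = document.getElementById('ppipath-svg');
  var W = 760, H = 520;
  var nodes = data.nodes.map(function (n, i) {
    var a = 2 * Math.PI * i / Math.max(1, data.nodes.length);
    return {d: n, x: W / 2 + 180 * Math.cos(a), y: H / 2 + 180 * Math.sin(a),
            vx: 0, vy: 0};
  });
  var index = {};
  nodes.forEach(function (n) { index[n.d.id] = n; });
  var links = data.links.map(function (l) {
    return {s: index[l.source], t: index[l.target], d: l};
  }).filter(function (l) { return l.s && l.t; });
  function step() {
    var i, j, k;
    for (i = 0; i < nodes.length; i++) {
      for (j = i + 1; j < nodes.length; j++) {
        var dx = nodes[j].x - nodes[i].x, dy = nodes[j].y - nodes[i].y;
        var d2 = Math.max(64, dx * dx + dy * dy), f = 1800 / d2;
        var d = Math.sqrt(d2);
        nodes[i].vx -= f * dx / d; nodes[i].vy -= f * dy / d;
        nodes[j].vx += f * dx / d; nodes[j].vy += f * dy / d;
      }
    }
    links.forEach(function (l) {
      var dx = l.t.x - l.s.x, dy = l.t.y - l.s.y;
      var d = Math.max(1, Math.sqrt(dx * dx + dy * dy));
      var f = 0.02 * (d - 90);
      l.s.vx += f * dx / d; l.s.vy += f * dy / d;
      l.t.vx -= f * dx / d; l.t.vy -= f * dy / d;
    });
    nodes.forEach(function (n) {
      n.vx += (W / 2 - n.x) * 0.002; n.vy += (H / 2 - n.y) * 0.002;
      n.x += n.vx *= 0.85; n.y += n.vy *= 0.85;
      n.x = Math.min(W - 20, Math.max(20, n.x));
      n.y = Math.min(H - 20, Math.max(20, n.y));
    });
  }
  for (var it = 0; it < 300; it++) step();
  var NS = 'http://www.w3.org/2000/svg';
  links.forEach(function (l) {
    var e = document.createElementNS(NS, 'line');
    e.setAttribute('x1', l.s.x); e.setAttribute('y1', l.s.y);
    e.setAttribute('x2', l.t.x); e.setAttribute('y2', l.t.y);
    e.setAttribute('class', 'edge');
    var t = document.createElementNS(NS, 'title');
    t.textContent = l.d.evidence;
    e.appendChild(t);
    svg.appendChild(e);
  });
  nodes.forEach(function (n) {
    var g = document.createElementNS(NS, 'a');
    g.setAttribute('href', n.d.href);
    var c = document.createElementNS(NS, 'circle');
    c.setAttribute('cx', n.x); c.setAttribute('cy', n.y);
    c.setAttribute('r', n.d.size_class === 'large' ? 14 : 8);
    c.setAttribute('class', 'node ' + n.d.color_class);
    var t = document.createElementNS(NS, 'text');
    t.setAttribute('x', n.x); t.setAttribute('y', n.y - 16);
    t.setAttribute('class', 'label');
    t.textContent = n.d.label;
    g.appendChild(c); g.appendChild(t); svg.appendChild(g);
  });
})();
"

#' Render a view document as a self-contained HTML page
#'
#' Writes a single HTML file embedding the document data (as a JSON block),
#' an inline force-directed layout script, and the evidence table, so the
#' page can be opened directly from a local disk, web server, or cloud
#' drive with no further assets. Rendering is deterministic: the same
#' document always produces a byte-identical file.
#'
#' @param doc A `ppi_view_document`.
#' @param out Output HTML file path.
#' @return Invisibly, `out`.
#' @export
render_html <- function(doc, out) {
  stopifnot(inherits(doc, "ppi_view_document"))
  dir <- dirname(out)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot write to '%s': directory does not exist", out),
          class = "ppipath_io_error")
  }
  json <- as.character(doc_to_json(doc))
  json <- gsub("</", "<\\/", json, fixed = TRUE)  # keep the script block intact

  ev <- doc$evidence
  ev_rows <- if (nrow(ev)) {
    paste0(
      "<tr><td>", html_escape(ev$acc_a), "</td><td>", html_escape(ev$acc_b),
      "</td><td>", html_escape(ev$sources), "</td><td>",
      html_escape(gsub(";", ", ", ev$pmids)), "</td><td>",
      ifelse(is.na(ev$string_score), "", as.character(ev$string_score)),
      "</td><td>", sprintf("%.6g", ev$cost), "</td></tr>",
      collapse = "\n"
    )
  } else ""
  path_rows <- if (!is.null(doc$paths) && length(doc$paths)) {
    paste0("<li>", vapply(doc$paths, function(p)
      html_escape(paste(p, collapse = " → ")), character(1)),
      "</li>", collapse = "\n")
  } else ""

  page <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>Protein interaction network view</title>\n",
    "<style>\n",
    "body{font-family:sans-serif;margin:1em;}\n",
    ".edge{stroke:#999;stroke-width:1.2px;}\n",
    ".node.main{fill:#2b6cb0;}.node.leaf{fill:#38a169;}.node.path{fill:#38a169;}\n",
    ".label{font-size:10px;text-anchor:middle;fill:#333;}\n",
    "table{border-collapse:collapse;}td,th{border:1px solid #ccc;padding:2px 6px;}\n",
    "</style>\n</head>\n<body>\n",
    "<h1>Protein interaction network view</h1>\n",
    "<svg id=\"ppipath-svg\" width=\"760\" height=\"520\"></svg>\n",
    if (nzchar(path_rows))
      paste0("<h2>Shortest paths</h2>\n<ol>\n", path_rows, "\n</ol>\n") else "",
    "<h2>Evidence</h2>\n",
    "<table>\n<tr><th>Protein A</th><th>Protein B</th><th>Databases</th>",
    "<th>PubMed IDs</th><th>STRING score</th><th>Cost</th></tr>\n",
    ev_rows, "\n</table>\n",
    "<script id=\"ppipath-data\" type=\"application/json\">", json, "</script>\n",
    "<script>", FORCE_LAYOUT_JS, "</script>\n",
    "</body>\n</html>"
  )
  write_lines_lf(page, out)
}
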