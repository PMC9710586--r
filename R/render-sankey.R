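#' Sankey graph JSON sidecar
#'
#' The sidecar is the lossless on-disk form of a [build_sankey_graph()]
#' result: `{"nodes": [{id, layer, label}], "links": [{source, target,
#' weight, sign}]}`. `read_sankey_json(write_sankey_json(g))` reproduces `g`
#' exactly.
#'
#' @param graph A `sankey_graph`.
#' @param path Output path.
#' @export
write_sankey_json <- function(graph, path) {
  stopifnot(inherits(graph, "sankey_graph"))
  jsonlite::write_json(list(nodes = graph$nodes, links = graph$links),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_sankey_json
#' @export
read_sankey_json <- function(path) {
  if (!file.exists(path))
    csea_stop(sprintf("file not found: %s", path), "csea_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- empty_sankey_graph()
  if (length(obj$nodes)) g$nodes <- as.data.frame(obj$nodes)[c("id", "layer", "label")]
  if (length(obj$links)) {
    g$links <- as.data.frame(obj$links)[c("source", "target", "weight", "sign")]
    g$links$weight <- as.numeric(g$links$weight)
    g$links$sign <- as.numeric(g$links$sign)
  }
  g
}

#' Render a Sankey graph as self-contained interactive HTML
#'
#' Writes one HTML document with an embedded SVG renderer (no external
#' assets, works offline) drawing the three layers left to right in the
#' order level, feature, task, link ribbons proportional to weight, hover
#' highlighting, and optional weight labels — plus a JSON sidecar (same
#' basename, `.json`) that round-trips losslessly via [read_sankey_json()].
#' An empty graph produces a valid page with an empty-diagram notice.
#'
#' @param graph A `sankey_graph` from [build_sankey_graph()].
#' @param output_path Path of the HTML file to write.
#' @param colors Named character vector of fill colors per layer.
#' @param node_padding Vertical gap between nodes, in pixels.
#' @param show_weights Draw the link weight next to each ribbon on hover.
#' @param title Page title.
#' @return Invisibly, a list with the `html` and `json` paths.
#' @export
render_sankey <- function(graph, output_path,
                          colors = c(level = "#66c2a5", feature = "#8da0cb",
                                     task = "#fc8d62"),
                          node_padding = 6, show_weights = TRUE,
                          title = "Intersecting-set Sankey diagram") {
  stopifnot(inherits(graph, "sankey_graph"))
  json_path <- sub("\\.html?$", ".json", output_path, ignore.case = TRUE)
  if (identical(json_path, output_path)) json_path <- paste0(output_path, ".json")
  write_sankey_json(graph, json_path)
  payload <- jsonlite::toJSON(
    list(nodes = graph$nodes, links = graph$links,
         options = list(colors = as.list(colors),
                        node_padding = node_padding,
                        show_weights = isTRUE(show_weights))),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title>", title),
    "<style>",
    "body{font-family:sans-serif;margin:20px}",
    ".link{fill:none;opacity:.45}.link:hover{opacity:.85}",
    ".node text{font-size:11px}.notice{color:#888;font-style:italic}",
    "</style></head><body>",
    sprintf("<h3>%s</h3>", title),
    "<div id=\"sankey\"></div>",
    "<script type=\"application/json\" id=\"sankey-data\">",
    as.character(payload),
    "</script>",
    "<script>",
    sankey_js(),
    "</script>",
    "</body></html>")
  ok <- tryCatch({ writeLines(html, output_path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    csea_stop(sprintf("cannot write %s", output_path), "csea_io_error")
  invisible(list(html = output_path, json = json_path))
}

# Minimal dependency-free SVG Sankey renderer. Three fixed columns
# (level, feature, task); node heights proportional to through-flow; links
# drawn as cubic ribbons. Kept deliberately simple: legibility for many
# features, few tasks/levels.
sankey_js <- function() {
  '
(function () {
  var data = JSON.parse(document.getElementById("sankey-data").textContent);
  var host = document.getElementById("sankey");
  if (!data.nodes.length) {
    host.innerHTML = "<p class=\\"notice\\">Empty diagram: no link exceeds the threshold.</p>";
    return;
  }
  var layers = ["level", "feature", "task"];
  var pad = data.options.node_padding || 6;
  var flow = {};
  data.links.forEach(function (l) {
    flow[l.source] = (flow[l.source] || 0) + l.weight;
    flow[l.target] = (flow[l.target] || 0) + l.weight;
  });
  var byLayer = layers.map(function (ly) {
    return data.nodes.filter(function (n) { return n.layer === ly; });
  });
  var maxN = Math.max.apply(null, byLayer.map(function (c) { return c.length; }));
  var H = Math.max(360, maxN * (14 + pad)), W = 860;
  var colX = { level: 40, feature: W / 2 - 60, task: W - 160 };
  var nodeW = 14, pos = {};
  byLayer.forEach(function (col) {
    var total = col.reduce(function (a, n) { return a + (flow[n.id] || 1); }, 0);
    var free = H - pad * (col.length + 1);
    var y = pad;
    col.forEach(function (n) {
      var h = Math.max(4, free * ((flow[n.id] || 1) / total));
      pos[n.id] = { x: colX[n.layer], y: y, h: h, outY: y, inY: y };
      y += h + pad;
    });
  });
  function esc(s) { return String(s).replace(/&/g, "&amp;").replace(/</g, "&lt;"); }
  var svg = ["<svg xmlns=\\"http://www.w3.org/2000/svg\\" width=\\"" + W +
             "\\" height=\\"" + H + "\\">"];
  data.links.forEach(function (l) {
    var s = pos[l.source], t = pos[l.target];
    if (!s || !t) return;
    var wScale = function (p) {
      return Math.max(1, p.h * (l.weight / (flow[l.source] || 1)));
    };
    var w = Math.max(1, Math.min(s.h, t.h) * 0.9 *
                     (l.weight / Math.max(flow[l.source], flow[l.target])));
    var x1 = s.x + nodeW, x2 = t.x, y1 = s.outY + w / 2, y2 = t.inY + w / 2;
    s.outY += w; t.inY += w;
    var mx = (x1 + x2) / 2;
    var color = l.sign < 0 ? "#b2182b" : "#2166ac";
    svg.push("<path class=\\"link\\" stroke=\\"" + color + "\\" stroke-width=\\"" +
             w + "\\" d=\\"M" + x1 + "," + y1 + " C" + mx + "," + y1 + " " +
             mx + "," + y2 + " " + x2 + "," + y2 + "\\">" +
             (data.options.show_weights ?
              "<title>" + esc(l.source) + " \\u2192 " + esc(l.target) +
              ": " + l.weight.toPrecision(4) + "</title>" : "") + "</path>");
  });
  data.nodes.forEach(function (n) {
    var p = pos[n.id];
    if (!p) return;
    var fill = (data.options.colors && data.options.colors[n.layer]) || "#999";
    var tx = n.layer === "task" ? p.x + nodeW + 4 : p.x - 4;
    var anchor = n.layer === "task" ? "start" : "end";
    svg.push("<g class=\\"node\\"><rect x=\\"" + p.x + "\\" y=\\"" + p.y +
             "\\" width=\\"" + nodeW + "\\" height=\\"" + p.h +
             "\\" fill=\\"" + fill + "\\"><title>" + esc(n.label) +
             "</title></rect>" +
             "<text x=\\"" + tx + "\\" y=\\"" + (p.y + p.h / 2 + 4) +
             "\\" text-anchor=\\"" + anchor + "\\">" + esc(n.label) +
             "</text></g>");
  });
  svg.push("</svg>");
  host.innerHTML = svg.join("");
})();
'
}
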