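#' Build a three-layer intersecting-set Sankey graph
#'
#' Every cube entry with `|value| > threshold` contributes its magnitude to
#' two links: level -> feature and feature -> task. Parallel links between
#' the same node pair are merged by summing magnitudes; the sign attribute is
#' the sign of the summed raw coefficients (0 if they cancel exactly). Nodes
#' exist only where a surviving link touches them, so unselected labels are
#' dropped.
#'
#' By construction each feature node conserves flow: its level-side total
#' weight equals its task-side total weight equals the summed magnitude of
#' its surviving entries.
#'
#' @param cube A [coefficient_cube()].
#' @param threshold Nonnegative magnitude cutoff; 0 (default) keeps strict
#'   nonzeros, matching estimators that produce exact zeros.
#' @return A `sankey_graph`: list with data.frames `nodes` (`id`, `layer`,
#'   `label`) and `links` (`source`, `target`, `weight`, `sign`). Node ids
#'   are layer-qualified (`"level:..."`, `"feature:..."`, `"task:..."`) so
#'   labels may repeat across layers.
#' @examples
#' cube <- make_sparse_cube(3, 10, 2, density = 0.2, seed = 1)
#' g <- build_sankey_graph(cube)
#' nrow(g$links)
#' @export
build_sankey_graph <- function(cube, threshold = 0) {
  stopifnot(inherits(cube, "coefficient_cube"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    csea_stop("`threshold` must be a single nonnegative number",
              "csea_contract_error")
  dn <- dimnames(cube)
  keep <- which(abs(cube) > threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    csea_warn("no cube entry exceeds the threshold: empty Sankey graph",
              "csea_empty_graph_warning")
    return(empty_sankey_graph())
  }
  val <- cube[keep]
  lev <- dn[[1]][keep[, 1]]
  fea <- dn[[2]][keep[, 2]]
  tas <- dn[[3]][keep[, 3]]

  merge_links <- function(src, dst) {
    key <- paste(src, dst, sep = "\r")
    w <- tapply(abs(val), key, sum)
    raw <- tapply(val, key, sum)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    data.frame(source = vapply(parts, `[`, "", 1),
               target = vapply(parts, `[`, "", 2),
               weight = as.numeric(w),
               sign = sign(as.numeric(raw)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  links <- rbind(merge_links(paste0("level:", lev), paste0("feature:", fea)),
                 merge_links(paste0("feature:", fea), paste0("task:", tas)))
  links <- links[order(links$source, links$target), , drop = FALSE]
  rownames(links) <- NULL

  ids <- unique(c(links$source, links$target))
  layer <- sub(":.*$", "", ids)
  nodes <- data.frame(id = ids, layer = layer,
                      label = sub("^[a-z]+:", "", ids),
                      stringsAsFactors = FALSE)
  ord <- order(match(nodes$layer, c("level", "feature", "task")), nodes$label)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, links = links), class = "sankey_graph")
}

empty_sankey_graph <- function() {
  structure(list(
    nodes = data.frame(id = character(), layer = character(),
                       label = character(), stringsAsFactors = FALSE),
    links = data.frame(source = character(), target = character(),
                       weight = numeric(), sign = numeric(),
                       stringsAsFactors = FALSE)),
    class = "sankey_graph")
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat(sprintf("<sankey_graph> %d node(s), %d link(s)\n",
              nrow(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Number of possible intersection patterns
#'
#' A feature selected by a multitask multilevel model belongs to one of
#' `(2^m - 1) * (2^T - 1)` intersecting sets: a nonempty subset of the m
#' tasks paired with a nonempty subset of the T levels.
#'
#' @param m Number of tasks (>= 1).
#' @param T_levels Number of levels (>= 1).
#' @return The pattern count as a double (exact for the small m, T of
#'   practical diagrams).
#' @examples
#' count_intersection_patterns(2, 3)  # 21
#' @export
count_intersection_patterns <- function(m, T_levels) {
  m <- as.integer(m); T_levels <- as.integer(T_levels)
  if (is.na(m) || is.na(T_levels) || m < 1 || T_levels < 1)
    csea_stop("`m` and `T_levels` must be positive integers",
              "csea_contract_error")
  (2^m - 1) * (2^T_levels - 1)
}

#' Intersection pattern of one feature
#'
#' The (task subset, level subset) a feature is associated with: the tasks
#' with any entry of magnitude above the threshold in the feature's slice,
#' and likewise the levels. Both empty means the feature is unselected.
#'
#' @inheritParams build_sankey_graph
#' @param feature_id A feature label present in the cube.
#' @return List with character vectors `tasks` and `levels`.
#' @export
assign_intersection_pattern <- function(cube, feature_id, threshold = 0) {
  stopifnot(inherits(cube, "coefficient_cube"))
  dn <- dimnames(cube)
  j <- match(as.character(feature_id), dn[[2]])
  if (is.na(j))
    csea_stop(sprintf("unknown feature '%s'", feature_id),
              "csea_lookup_error")
  slice <- abs(cube[, j, , drop = FALSE]) > threshold  # T x 1 x m
  list(tasks = dn[[3]][apply(slice, 3, any)],
       levels = dn[[1]][apply(slice, 1, any)])
}
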