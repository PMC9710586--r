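#' @name io
#' @title Reading and writing scores, sets, results and cubes
#'
#' @description
#' All external representations are plain UTF-8 text. Scores travel as
#' delimited tables (first column feature id, one further column per
#' phenotype, header required); sets as GMT (one set per line:
#' id, description, members, tab-separated) or a two-column long membership
#' table; results as a tidy TSV; coefficient cubes as long-format TSV
#' (`level_id`, `feature_id`, `task_id`, `coefficient`). The delimiter is
#' auto-detected from the extension (`.csv` = comma, otherwise tab) with an
#' explicit override. Readers attach a `parse_report` attribute
#' (`n_records`, `n_dropped`, `warnings`), retrievable with
#' [parse_report()].
NULL

detect_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

make_report <- function(n_records, n_dropped = 0L, warnings = character()) {
  list(n_records = as.integer(n_records), n_dropped = as.integer(n_dropped),
       warnings = warnings)
}

#' @rdname io
#' @param x An object returned by one of the readers.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' @rdname io
#' @param path File path.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @return `read_scores()`: a [ranked_scores()] object.
#' @export
read_scores <- function(path, delimiter = NULL) {
  if (!file.exists(path))
    csea_stop(sprintf("file not found: %s", path), "csea_io_error")
  delim <- detect_delim(path, delimiter)
  df <- tryCatch(
    read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, colClasses = "character",
               fileEncoding = "UTF-8"),
    error = function(e) csea_stop(sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e)),
                                  "csea_parse_error"))
  if (nrow(df) == 0 || ncol(df) < 2)
    csea_stop("scores file needs a feature-id column plus >= 1 phenotype column",
              "csea_parse_error")
  ids <- df[[1]]
  vals <- df[-1]
  num <- suppressWarnings(lapply(vals, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(vals[[j]]))
    if (length(bad))
      csea_stop(sprintf("non-numeric score at row %d, column '%s'",
                        bad[1], names(vals)[j]),
                "csea_parse_error")
  }
  m <- do.call(cbind, num)
  colnames(m) <- names(vals)
  rs <- ranked_scores(m, feature_ids = ids)
  attr(rs, "parse_report") <- make_report(nrow(df))
  rs
}

#' @rdname io
#' @param scores A [ranked_scores()] object.
#' @param id_column Header name of the feature-id column on write.
#' @export
write_scores <- function(scores, path, delimiter = NULL,
                         id_column = "feature_id") {
  stopifnot(inherits(scores, "ranked_scores"))
  delim <- detect_delim(path, delimiter)
  # %.17g preserves doubles exactly through the text round-trip
  body <- as.data.frame(lapply(seq_len(ncol(scores)),
                               function(j) sprintf("%.17g", scores[, j])))
  names(body) <- colnames(scores)
  df <- data.frame(rownames(scores), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @param format `"auto"` (by extension: `.gmt` vs table), `"gmt"`, or
#'   `"long"` (two-column membership table with header
#'   `feature_id`, `set_id`).
#' @return `read_sets()`: a [set_collection()].
#' @export
read_sets <- function(path, format = c("auto", "gmt", "long"),
                      delimiter = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    csea_stop(sprintf("file not found: %s", path), "csea_io_error")
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "long"
  if (format == "gmt") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0)
      csea_stop("empty GMT file", "csea_parse_error")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3)
    if (length(short))
      csea_stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                        short[1]),
                "csea_parse_error")
    ids <- vapply(fields, `[`, "", 1)
    desc <- stats::setNames(vapply(fields, `[`, "", 2), ids)
    members <- lapply(fields, function(f) f[-(1:2)])
    names(members) <- ids
    sc <- suppressWarnings(set_collection(members, descriptions = desc))
    attr(sc, "parse_report") <-
      make_report(length(lines), warnings = if (attr(sc, "n_dedup") > 0)
        sprintf("%d duplicate membership(s) removed", attr(sc, "n_dedup"))
        else character())
    return(sc)
  }
  delim <- detect_delim(path, delimiter)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  sc <- suppressWarnings(set_collection(df))
  attr(sc, "parse_report") <-
    make_report(nrow(df), warnings = if (attr(sc, "n_dedup") > 0)
      sprintf("%d duplicate membership(s) removed", attr(sc, "n_dedup"))
      else character())
  sc
}

#' @rdname io
#' @param sets A [set_collection()].
#' @export
write_sets_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "set_collection"))
  desc <- attr(sets, "descriptions")
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname io
#' @param result A `csea_result` from [csea()].
#' @return `write_results()` invisibly returns the path; the file is a tidy
#'   TSV with columns `set_id`, `phenotype_id`, `set_size`, `es`, `nes`,
#'   `p_value`, `p_adjusted`, `significant`, numeric columns written at full
#'   double precision, deterministic row order.
#' @export
write_results <- function(result, path) {
  cols <- c("set_id", "phenotype_id", "set_size", "es", "nes",
            "p_value", "p_adjusted", "significant")
  df <- as.data.frame(result)[, cols, drop = FALSE]
  for (cn in c("es", "nes", "p_value", "p_adjusted"))
    df[[cn]] <- sprintf("%.17g", df[[cn]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname io
#' @return `read_results()`: a plain data.frame mirroring the written table.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    csea_stop(sprintf("file not found: %s", path), "csea_io_error")
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$significant <- as.logical(df$significant)
  df
}

#' @rdname io
#' @return `read_cube()`: a [coefficient_cube()] assembled from the long
#'   table; (level, feature, task) combinations absent from the file are 0.
#' @export
read_cube <- function(path, delimiter = NULL) {
  if (!file.exists(path))
    csea_stop(sprintf("file not found: %s", path), "csea_io_error")
  delim <- detect_delim(path, delimiter)
  df <- read.delim(path, sep = delim, header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  need <- c("level_id", "feature_id", "task_id", "coefficient")
  if (!all(need %in% names(df)))
    csea_stop(sprintf("cube table needs columns: %s",
                      paste(need, collapse = ", ")),
              "csea_parse_error")
  coef <- suppressWarnings(as.numeric(df$coefficient))
  bad <- which(is.na(coef))
  if (length(bad))
    csea_stop(sprintf("non-numeric coefficient at row %d", bad[1]),
              "csea_parse_error")
  lev <- unique(df$level_id); fea <- unique(df$feature_id)
  tas <- unique(df$task_id)
  a <- array(0, dim = c(length(lev), length(fea), length(tas)),
             dimnames = list(lev, fea, tas))
  a[cbind(match(df$level_id, lev), match(df$feature_id, fea),
          match(df$task_id, tas))] <- coef
  cube <- coefficient_cube(a)
  attr(cube, "parse_report") <- make_report(nrow(df))
  cube
}

#' @rdname io
#' @param cube A [coefficient_cube()].
#' @param keep_zeros Write all cells (`TRUE`, lossless for dense cubes) or
#'   only nonzeros (`FALSE`, compact; absent cells read back as 0).
#' @export
write_cube <- function(cube, path, delimiter = NULL, keep_zeros = FALSE) {
  stopifnot(inherits(cube, "coefficient_cube"))
  delim <- detect_delim(path, delimiter)
  dn <- dimnames(cube)
  idx <- if (keep_zeros) {
    as.matrix(expand.grid(seq_along(dn[[1]]), seq_along(dn[[2]]),
                          seq_along(dn[[3]])))
  } else {
    which(cube != 0, arr.ind = TRUE)
  }
  df <- data.frame(level_id = dn[[1]][idx[, 1]],
                   feature_id = dn[[2]][idx[, 2]],
                   task_id = dn[[3]][idx[, 3]],
                   coefficient = sprintf("%.17g", cube[idx]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$level_id, df$feature_id, df$task_id), , drop = FALSE]
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
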