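#' Scored feature lists
#'
#' A `ranked_scores` object holds a real-valued rank metric for L features
#' across one or more phenotypes: a numeric matrix with feature ids as row
#' names and phenotype ids as column names. A named numeric vector is treated
#' as a single phenotype.
#'
#' @param scores Named numeric vector (one phenotype) or numeric matrix /
#'   data.frame (features in rows, phenotypes in columns).
#' @param feature_ids Optional character vector of feature identifiers;
#'   required when `scores` carries no names.
#' @param phenotype_ids Optional character vector of phenotype identifiers;
#'   defaults to existing column names or `"phenotype1"`, ... .
#' @return A `ranked_scores` object: a numeric matrix with attributes.
#' @examples
#' rs <- ranked_scores(c(A = 1.2, B = -0.5, C = 2.0))
#' n_features(rs)
#' @export
ranked_scores <- function(scores, feature_ids = NULL, phenotype_ids = NULL) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.vector(scores) && is.numeric(scores)) {
    if (is.null(feature_ids)) feature_ids <- names(scores)
    scores <- matrix(as.numeric(scores), ncol = 1)
  }
  if (!is.matrix(scores) || !is.numeric(scores))
    csea_stop("`scores` must be a numeric vector or matrix",
              "csea_validation_error")
  if (is.null(feature_ids)) feature_ids <- rownames(scores)
  if (is.null(feature_ids))
    csea_stop("feature ids are required (names, rownames or `feature_ids`)",
              "csea_validation_error")
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != nrow(scores))
    csea_stop("length of `feature_ids` does not match the number of rows",
              "csea_validation_error")
  if (anyDuplicated(feature_ids))
    csea_stop(sprintf("duplicated feature ids: %s",
                      paste(unique(feature_ids[duplicated(feature_ids)]),
                            collapse = ", ")),
              "csea_validation_error")
  if (nrow(scores) < 2)
    csea_stop("at least two features are required", "csea_validation_error")
  if (is.null(phenotype_ids)) phenotype_ids <- colnames(scores)
  if (is.null(phenotype_ids))
    phenotype_ids <- paste0("phenotype", seq_len(ncol(scores)))
  phenotype_ids <- as.character(phenotype_ids)
  if (anyDuplicated(phenotype_ids) || length(phenotype_ids) != ncol(scores))
    csea_stop("phenotype ids must be unique, one per score column",
              "csea_validation_error")
  bad <- !is.finite(scores)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    csea_stop(sprintf("non-finite score for feature '%s' (phenotype '%s')",
                      feature_ids[idx[1]], phenotype_ids[idx[2]]),
              "csea_validation_error")
  }
  dimnames(scores) <- list(feature_ids, phenotype_ids)
  structure(scores, class = c("ranked_scores", "matrix", "array"))
}

#' @rdname ranked_scores
#' @param x A `ranked_scores` object.
#' @export
n_features <- function(x) nrow(x)

#' @rdname ranked_scores
#' @export
n_phenotypes <- function(x) ncol(x)

#' @export
print.ranked_scores <- function(x, ...) {
  cat(sprintf("<ranked_scores> %d features x %d phenotype(s)\n",
              nrow(x), ncol(x)))
  print(head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more features\n", nrow(x) - 6L))
  invisible(x)
}

#' Order one phenotype's scores ascending
#'
#' Returns the permutation of `1:L` that places features in ascending score
#' order (position 1 = smallest score, position L = largest), the indexing
#' convention of the running-sum statistic. Ties keep their original input
#' order (stable sort).
#'
#' @param scores Numeric vector of finite scores, length >= 2.
#' @return Integer permutation of `seq_along(scores)`.
#' @examples
#' rank_features(c(A = 4, B = 3, C = 2, D = 1))  # 4 3 2 1
#' @export
rank_features <- function(scores) {
  nm <- names(scores)
  scores <- as.numeric(scores)
  if (length(scores) < 2)
    csea_stop("at least two scores are required", "csea_validation_error")
  bad <- which(!is.finite(scores))
  if (length(bad)) {
    who <- if (is.null(nm)) paste0("#", bad[1]) else nm[bad[1]]
    csea_stop(sprintf("non-finite score for feature %s", who),
              "csea_validation_error")
  }
  order(scores, method = "radix")  # radix order is stable in ties
}
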