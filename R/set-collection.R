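#' User-defined custom set collections
#'
#' A `set_collection` maps set ids to member feature ids. Construction from a
#' named list of character vectors or from a two-column long membership table
#' (`feature_id`, `set_id`). Duplicate members within a set are removed with a
#' warning; empty sets are rejected.
#'
#' Validation against a feature universe (the feature ids of a companion
#' [ranked_scores()]) is performed by [validate_sets()] — every member must be
#' present in the universe, and each retained set must satisfy
#' `1 <= L_k < L` so that its complement is nonempty.
#'
#' @param sets Named list of character vectors, or a data.frame with columns
#'   `feature_id` and `set_id` (extra columns ignored).
#' @param descriptions Optional named character vector of set descriptions
#'   (kept for GMT round-trips, otherwise unused).
#' @return A `set_collection`: a named list of character member vectors with
#'   a `descriptions` attribute and a `n_dedup` attribute counting removed
#'   duplicate memberships.
#' @examples
#' sc <- set_collection(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
#' lengths(sc)
#' @export
set_collection <- function(sets, descriptions = NULL) {
  if (is.data.frame(sets)) {
    need <- c("feature_id", "set_id")
    if (!all(need %in% names(sets)))
      csea_stop("long membership table needs columns feature_id and set_id",
                "csea_validation_error")
    sets <- split(as.character(sets$feature_id), as.character(sets$set_id))
  }
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    csea_stop("`sets` must be a named list or a long membership table",
              "csea_validation_error")
  if (anyDuplicated(names(sets)))
    csea_stop("set ids must be unique", "csea_validation_error")
  n_dedup <- 0L
  sets <- lapply(sets, function(members) {
    members <- as.character(members)
    dup <- duplicated(members)
    n_dedup <<- n_dedup + sum(dup)
    members[!dup]
  })
  if (n_dedup > 0)
    csea_warn(sprintf("%d duplicate membership(s) removed", n_dedup),
              "csea_dedup_warning")
  if (any(lengths(sets) == 0))
    csea_stop(sprintf("empty set(s): %s",
                      paste(names(sets)[lengths(sets) == 0], collapse = ", ")),
              "csea_validation_error")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep(NA_character_, length(sets)),
                                    names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, n_dedup = n_dedup,
            class = c("set_collection", "list"))
}

#' @export
print.set_collection <- function(x, ...) {
  cat(sprintf("<set_collection> %d set(s), sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' @rdname set_collection
#' @param x A `set_collection`.
#' @param universe Character vector of feature ids defining the ranked-list
#'   universe.
#' @param unknown_feature_policy `"error"` (default: any member absent from
#'   the universe aborts, listing the offenders) or `"drop_with_warning"`.
#' @param min_set_size Sets with fewer retained members are dropped with a
#'   warning.
#' @export
validate_sets <- function(x, universe,
                          unknown_feature_policy = c("error",
                                                     "drop_with_warning"),
                          min_set_size = 2L) {
  stopifnot(inherits(x, "set_collection"))
  unknown_feature_policy <- match.arg(unknown_feature_policy)
  universe <- as.character(universe)
  L <- length(universe)
  unknown <- lapply(x, function(m) setdiff(m, universe))
  n_unknown <- sum(lengths(unknown))
  if (n_unknown > 0) {
    if (unknown_feature_policy == "error") {
      csea_stop(sprintf(
        "set member(s) not present in the ranked list: %s",
        paste(unique(unlist(unknown)), collapse = ", ")),
        "csea_unknown_feature_error")
    }
    csea_warn(sprintf("%d unknown member(s) dropped", n_unknown),
              "csea_unknown_feature_warning")
  }
  kept <- lapply(x, function(m) intersect(m, universe))
  small <- lengths(kept) < min_set_size
  full <- lengths(kept) >= L  # complement would be empty
  drop <- small | full
  if (any(drop))
    csea_warn(sprintf(
      "dropping %d set(s) with size outside [%d, %d]: %s",
      sum(drop), min_set_size, L - 1L,
      paste(names(kept)[drop], collapse = ", ")),
      "csea_set_size_warning")
  kept <- kept[!drop]
  if (length(kept) == 0)
    csea_stop("no set survives validation; nothing to test",
              "csea_nothing_to_test_error")
  set_collection(kept, descriptions = attr(x, "descriptions"))
}
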