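#' Custom set enrichment analysis
#'
#' Scores every (set, phenotype) pair: ranks the phenotype's scores
#' ascending, computes the weighted KS enrichment score, draws a
#' set-permutation null (shared between sets of equal size within a
#' phenotype — the null depends only on the set size), derives the empirical
#' p-value and the normalized enrichment score, and finally adjusts p-values
#' jointly across all pairs.
#'
#' Each phenotype uses an independent RNG stream derived from `config$seed`,
#' so adding or reordering phenotypes does not change another phenotype's
#' permutations.
#'
#' @param scores A [ranked_scores()] object, or anything its constructor
#'   accepts (named vector, matrix, data.frame).
#' @param sets A [set_collection()], named list, or long membership table.
#' @param config A [csea_config()].
#' @return A `csea_result` data.frame with one row per (set, phenotype):
#'   `set_id`, `phenotype_id`, `set_size`, `es`, `nes`, `p_value`,
#'   `p_adjusted`, `significant`, `null_mean`, `which_max`, `direction`,
#'   `n_perm`; ordered by phenotype then descending NES. The configuration is
#'   attached as attribute `config`.
#' @examples
#' inst <- make_planted_instance(L = 60, n_sets = 4, set_size_range = c(5, 10),
#'                               shift = 2, seed = 1)
#' res <- csea(inst$scores, inst$sets, csea_config(n_perm = 50, seed = 1))
#' head(res)
#' @export
csea <- function(scores, sets, config = csea_config()) {
  stopifnot(inherits(config, "csea_config"))
  if (!inherits(scores, "ranked_scores")) scores <- ranked_scores(scores)
  if (!inherits(sets, "set_collection")) sets <- set_collection(sets)
  universe <- rownames(scores)
  sets <- validate_sets(sets, universe,
                        unknown_feature_policy = config$unknown_feature_policy,
                        min_set_size = config$min_set_size)
  L <- nrow(scores)
  set_ids <- names(sets)
  phen_ids <- colnames(scores)
  member_idx <- lapply(sets, function(m) match(m, universe))
  sizes <- lengths(member_idx)

  rows <- vector("list", length(phen_ids))
  for (pi in seq_along(phen_ids)) {
    col <- as.numeric(scores[, pi])
    ord <- rank_features(stats::setNames(col, universe))
    s_ord <- col[ord]
    pos_of <- integer(L); pos_of[ord] <- seq_len(L)  # feature row -> list position
    w <- abs(s_ord)^config$alpha

    es <- numeric(length(set_ids))
    which_max <- integer(length(set_ids))
    direction <- numeric(length(set_ids))
    for (si in seq_along(set_ids)) {
      hit_idx <- pos_of[member_idx[[si]]]
      memb <- logical(L); memb[hit_idx] <- TRUE
      F <- weighted_ecdfs(s_ord, memb, alpha = config$alpha,
                          mode = config$miss_ecdf_mode)
      e <- enrichment_score(F$F_hit, F$F_miss)
      es[si] <- as.numeric(e)
      which_max[si] <- attr(e, "which_max")
      direction[si] <- attr(e, "direction")
    }

    # One null per distinct set size, drawn in ascending size order so the
    # stream is independent of how the user ordered the sets.
    phen_seed <- derive_seed(config$seed, pi)
    nulls <- new.env(parent = emptyenv())
    draw_all <- function() {
      for (sz in sort(unique(sizes))) {
        assign(as.character(sz),
               vapply(seq_len(config$n_perm), function(b) {
                 .es_at(w, L, sample.int(L, sz), config$miss_ecdf_mode)
               }, numeric(1)),
               envir = nulls)
      }
    }
    if (is.null(phen_seed)) draw_all() else with_seed(phen_seed, draw_all())

    p <- numeric(length(set_ids)); nes <- numeric(length(set_ids))
    null_mean <- numeric(length(set_ids))
    for (si in seq_along(set_ids)) {
      nl <- get(as.character(sizes[si]), envir = nulls)
      p[si] <- empirical_pvalue(es[si], nl)
      null_mean[si] <- mean(nl)
      nes[si] <- normalized_score(es[si], nl)
    }
    rows[[pi]] <- data.frame(
      set_id = set_ids, phenotype_id = phen_ids[pi],
      set_size = as.integer(sizes), es = es, nes = nes, p_value = p,
      null_mean = null_mean, which_max = which_max, direction = direction,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- adjust_pvalues(res$p_value, config$correction_method)
  res$significant <- res$p_adjusted < config$sig_level
  res$n_perm <- config$n_perm
  res <- res[order(match(res$phenotype_id, phen_ids), -res$nes,
                   res$set_id), ]
  rownames(res) <- NULL
  res <- res[, c("set_id", "phenotype_id", "set_size", "es", "nes",
                 "p_value", "p_adjusted", "significant", "null_mean",
                 "which_max", "direction", "n_perm")]
  structure(res, config = config, class = c("csea_result", "data.frame"))
}

#' @export
print.csea_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<csea_result> %d (set, phenotype) pair(s); alpha=%g, n_perm=%d, %s correction\n",
    nrow(x), cfg$alpha, cfg$n_perm, cfg$correction_method))
  print.data.frame(head(x, 12L), digits = 4)
  if (nrow(x) > 12L) cat(sprintf("... %d more row(s)\n", nrow(x) - 12L))
  invisible(x)
}
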