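#' Weighted empirical cumulative distribution functions
#'
#' For a list of L scores already ordered ascending and a logical membership
#' vector marking the in-set ("hit") positions, computes the two running
#' curves whose largest absolute gap is the enrichment score.
#'
#' The hit curve accumulates `|s_t|^alpha` over in-set positions, normalized
#' by the total in-set weight, so it always ends at 1. The miss curve has two
#' dialects: `"classic"` accumulates plain counts over out-of-set positions
#' divided by `L - L_k` (a proper ECDF); `"as_printed"` accumulates
#' `|s_t|^alpha` over out-of-set positions but keeps the unweighted
#' denominator `L - L_k`, so for `alpha > 0` it need not end at 1. Both are
#' exposed because published descriptions of the statistic differ on this
#' point; `alpha = 0` makes them identical.
#'
#' @param ordered_scores Numeric vector of scores sorted ascending.
#' @param membership Logical vector, `TRUE` at in-set positions; needs at
#'   least one `TRUE` and one `FALSE`.
#' @param alpha Nonnegative weight exponent.
#' @param mode `"classic"` or `"as_printed"`.
#' @return List with numeric vectors `F_hit` and `F_miss`, each of length L.
#' @examples
#' weighted_ecdfs(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), alpha = 0)
#' @export
weighted_ecdfs <- function(ordered_scores, membership, alpha = 1,
                           mode = c("classic", "as_printed")) {
  mode <- match.arg(mode)
  membership <- as.logical(membership)
  L <- length(ordered_scores)
  if (length(membership) != L)
    csea_stop("`membership` length must match `ordered_scores`",
              "csea_contract_error")
  L_k <- sum(membership)
  if (L_k == 0L || L_k == L)
    csea_stop("degenerate set: membership must have hits and misses",
              "csea_degenerate_set_error")
  w <- abs(ordered_scores)^alpha
  hit_w <- w * membership
  denom <- sum(hit_w)
  if (denom <= 0)
    csea_stop("all in-set scores are zero with alpha > 0: hit-ECDF weight vanishes",
              "csea_degenerate_weight_error")
  F_hit <- cumsum(hit_w) / denom
  F_miss <- if (mode == "classic") {
    cumsum(!membership) / (L - L_k)
  } else {
    cumsum(w * !membership) / (L - L_k)
  }
  list(F_hit = F_hit, F_miss = F_miss)
}

#' Enrichment score from the two running curves
#'
#' The enrichment score S is the supremum over list positions of the absolute
#' gap between the in-set and out-of-set cumulative curves — a (weighted)
#' two-sample Kolmogorov--Smirnov statistic. The position of the supremum and
#' the sign of the gap there are attached as diagnostics (`which_max`,
#' `direction`); ties in the supremum resolve to the smallest position.
#'
#' @param F_hit,F_miss Equal-length numeric vectors from [weighted_ecdfs()].
#' @return The score (numeric scalar, >= 0) with attributes `which_max` and
#'   `direction`.
#' @examples
#' es <- enrichment_score(c(0, 0, 0.5, 1), c(0.5, 1, 1, 1))
#' as.numeric(es)          # 1
#' attr(es, "which_max")   # 2
#' @export
enrichment_score <- function(F_hit, F_miss) {
  if (length(F_hit) != length(F_miss) || length(F_hit) < 2)
    csea_stop("`F_hit` and `F_miss` must have equal length >= 2",
              "csea_contract_error")
  gap <- F_hit - F_miss
  a <- abs(gap)
  i <- which.max(a)  # first position on ties
  structure(a[i], which_max = i, direction = sign(gap[i]))
}

# Fast internal ES for the permutation loop: scores already ordered, w the
# precomputed |s|^alpha, hit_idx the in-set positions. Returns a bare number.
.es_at <- function(w, L, hit_idx, mode) {
  hit_w <- numeric(L)
  hit_w[hit_idx] <- w[hit_idx]
  denom <- sum(hit_w)
  if (denom <= 0)
    csea_stop("all in-set scores are zero with alpha > 0: hit-ECDF weight vanishes",
              "csea_degenerate_weight_error")
  F_hit <- cumsum(hit_w) / denom
  if (mode == "classic") {
    miss <- rep.int(1, L)
    miss[hit_idx] <- 0
    F_miss <- cumsum(miss) / (L - length(hit_idx))
  } else {
    miss_w <- w
    miss_w[hit_idx] <- 0
    F_miss <- cumsum(miss_w) / (L - length(hit_idx))
  }
  max(abs(F_hit - F_miss))
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `n_perm` pseudo-sets of size `set_size` uniformly at random (without
#' replacement) from the list positions and scores each against the same
#' ordered score vector. This set-permutation scheme is the null computable
#' from a standalone ranked list; it asks how extreme the observed score is
#' among random sets of the same size.
#'
#' @param ordered_scores Numeric vector sorted ascending.
#' @param set_size Pseudo-set size, `1 <= set_size < length(ordered_scores)`.
#' @param alpha Weight exponent.
#' @param mode Miss-curve dialect, see [weighted_ecdfs()].
#' @param n_perm Number of pseudo-sets.
#' @param seed Integer seed for reproducibility; `NULL` uses the ambient RNG.
#' @return Numeric vector of `n_perm` null scores.
#' @export
permutation_null <- function(ordered_scores, set_size, alpha = 1,
                             mode = c("classic", "as_printed"),
                             n_perm = 100L, seed = NULL) {
  mode <- match.arg(mode)
  L <- length(ordered_scores)
  set_size <- as.integer(set_size)
  if (set_size < 1L || set_size >= L)
    csea_stop("`set_size` must satisfy 1 <= set_size < L",
              "csea_degenerate_set_error")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L)
    csea_stop("`n_perm` must be >= 1", "csea_config_error")
  w <- abs(ordered_scores)^alpha
  with_seed(seed, vapply(seq_len(n_perm), function(b) {
    .es_at(w, L, sample.int(L, set_size), mode)
  }, numeric(1)))
}

#' Empirical permutation p-value
#'
#' Add-one corrected tail probability: `(1 + #{null >= observed}) /
#' (1 + n_perm)`. Ties count toward the tail; the smallest attainable value
#' is `1 / (n_perm + 1)`, never zero.
#'
#' @param observed Observed enrichment score.
#' @param null_scores Numeric vector of permutation null scores.
#' @return p-value in `(0, 1]`.
#' @examples
#' empirical_pvalue(0.7, c(0.5, 0.7, 0.9))  # (1 + 2) / 4
#' @export
empirical_pvalue <- function(observed, null_scores) {
  if (length(null_scores) == 0)
    csea_stop("`null_scores` must be nonempty", "csea_contract_error")
  (1 + sum(null_scores >= as.numeric(observed))) / (1 + length(null_scores))
}

#' Normalized enrichment score
#'
#' The observed score divided by the mean of its permutation null, making
#' scores comparable across sets of different sizes (larger sets have smaller
#' null scores; the ratio corrects for that).
#'
#' @inheritParams empirical_pvalue
#' @return `observed / mean(null_scores)`.
#' @export
normalized_score <- function(observed, null_scores) {
  if (length(null_scores) == 0)
    csea_stop("`null_scores` must be nonempty", "csea_contract_error")
  m <- mean(null_scores)
  if (m <= 0)
    csea_stop("null mean is zero; normalized score undefined",
              "csea_normalization_error")
  as.numeric(observed) / m
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] translating the package's method
#' names; `"none"` returns the input unchanged.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @param method One of `"benjamini_hochberg"`, `"bonferroni"`, `"holm"`,
#'   `"none"`.
#' @return Adjusted p-values, clipped to `<= 1`.
#' @export
adjust_pvalues <- function(p_values, method = "benjamini_hochberg") {
  map <- c(benjamini_hochberg = "BH", bonferroni = "bonferroni",
           holm = "holm", none = "none")
  if (length(method) != 1 || !method %in% names(map))
    csea_stop(sprintf("unknown correction method '%s'",
                      paste(method, collapse = ",")),
              "csea_config_error")
  if (any(p_values <= 0 | p_values > 1))
    csea_stop("p-values must lie in (0, 1]", "csea_contract_error")
  p.adjust(p_values, method = map[[method]])
}

#' Hypergeometric over-representation test
#'
#' For an unranked selection of features, tests whether a set is
#' over-represented among the selected features: the upper-tail probability
#' `P(X >= hits)` for `X ~ Hypergeometric(universe_size, set_size,
#' selection_size)`.
#'
#' @param hits_in_selection Number of selected features that belong to the set.
#' @param selection_size Number of selected features.
#' @param set_size Number of set members in the universe.
#' @param universe_size Total number of features.
#' @return The one-sided p-value.
#' @examples
#' overrepresentation_test(1, 1, 1, 10)  # 0.1
#' @export
overrepresentation_test <- function(hits_in_selection, selection_size,
                                    set_size, universe_size) {
  h <- as.integer(hits_in_selection); s <- as.integer(selection_size)
  k <- as.integer(set_size); N <- as.integer(universe_size)
  if (h < 0 || h > min(s, k) || k > N || s > N)
    csea_stop("inconsistent counts for the hypergeometric test",
              "csea_contract_error")
  phyper(h - 1L, k, N - k, s, lower.tail = FALSE)
}
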