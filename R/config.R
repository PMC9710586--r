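#' Enrichment analysis configuration
#'
#' Bundles the tunable parameters of [csea()].
#'
#' @param alpha Nonnegative weight exponent of the running-sum statistic.
#'   `alpha = 0` gives the classic unweighted two-sample KS statistic;
#'   `alpha = 1` (default) weights in-set steps by the score magnitude, the
#'   customary weighted-GSEA exponent.
#' @param n_perm Number of random pseudo-sets drawn for the permutation null
#'   (default 100).
#' @param miss_ecdf_mode `"classic"` (default): the out-of-set curve is the
#'   unweighted ECDF, so both curves are proper CDFs ending at 1.
#'   `"as_printed"`: the out-of-set curve keeps a weighted numerator over the
#'   unweighted denominator `L - L_k`, and for `alpha > 0` need not reach 1.
#'   See the methods vignette for why both dialects exist.
#' @param seed Integer master seed; each phenotype gets an independent stream
#'   derived from it. `NULL` uses the ambient RNG state (not reproducible).
#' @param sig_level Significance level applied to adjusted p-values, in
#'   (0, 1). Default 0.05.
#' @param correction_method One of `"benjamini_hochberg"` (default),
#'   `"bonferroni"`, `"holm"`, `"none"`.
#' @param min_set_size Smallest retained set size (default 2).
#' @param unknown_feature_policy `"error"` (default) or `"drop_with_warning"`
#'   for set members absent from the ranked list.
#' @return A `csea_config` list.
#' @export
csea_config <- function(alpha = 1, n_perm = 100L,
                        miss_ecdf_mode = c("classic", "as_printed"),
                        seed = NULL, sig_level = 0.05,
                        correction_method = c("benjamini_hochberg",
                                              "bonferroni", "holm", "none"),
                        min_set_size = 2L,
                        unknown_feature_policy = c("error",
                                                   "drop_with_warning")) {
  miss_ecdf_mode <- match.arg(miss_ecdf_mode)
  correction_method <- match.arg(correction_method)
  unknown_feature_policy <- match.arg(unknown_feature_policy)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    csea_stop("`alpha` must be a single nonnegative number",
              "csea_config_error")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1)
    csea_stop("`n_perm` must be a positive integer", "csea_config_error")
  if (!is.numeric(sig_level) || sig_level <= 0 || sig_level >= 1)
    csea_stop("`sig_level` must lie in (0, 1)", "csea_config_error")
  min_set_size <- as.integer(min_set_size)
  if (is.na(min_set_size) || min_set_size < 1)
    csea_stop("`min_set_size` must be a positive integer",
              "csea_config_error")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(alpha = alpha, n_perm = n_perm,
                 miss_ecdf_mode = miss_ecdf_mode, seed = seed,
                 sig_level = sig_level,
                 correction_method = correction_method,
                 min_set_size = min_set_size,
                 unknown_feature_policy = unknown_feature_policy),
            class = "csea_config")
}
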