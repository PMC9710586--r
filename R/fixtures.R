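#' Synthetic null instance: random scores, random sets
#'
#' Draws i.i.d. standard normal scores for `L` features (per phenotype) and
#' `n_sets` sets whose members are sampled uniformly without replacement,
#' independently of the scores — so every set is a true null set. Used for
#' calibration checks: p-values for any fixed set should be uniform on the
#' achievable grid.
#'
#' @param L Universe size (>= 4).
#' @param n_sets Number of sets.
#' @param set_size_range Integer interval `c(lo, hi)` within `[2, L - 1]`;
#'   each set's size is drawn uniformly from it.
#' @param n_phenotypes Number of independent score columns.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List with elements `scores` ([ranked_scores()]) and `sets`
#'   ([set_collection()]).
#' @export
make_null_instance <- function(L, n_sets, set_size_range = c(5L, 20L),
                               n_phenotypes = 1L, seed = NULL) {
  L <- as.integer(L)
  if (L < 4) csea_stop("L must be >= 4", "csea_contract_error")
  set_size_range <- as.integer(set_size_range)
  if (length(set_size_range) != 2 || set_size_range[1] < 2 ||
      set_size_range[2] > L - 1 || set_size_range[1] > set_size_range[2])
    csea_stop("`set_size_range` must lie within [2, L - 1]",
              "csea_contract_error")
  with_seed(seed, {
    feats <- sprintf("f%03d", seq_len(L))
    sc <- matrix(rnorm(L * n_phenotypes), nrow = L,
                 dimnames = list(feats,
                                 paste0("phenotype", seq_len(n_phenotypes))))
    size_choices <- seq(set_size_range[1], set_size_range[2])
    sizes <- if (length(size_choices) == 1L) {
      rep(size_choices, n_sets)
    } else {
      sample(size_choices, n_sets, replace = TRUE)
    }
    sets <- lapply(sizes, function(sz) sample(feats, sz))
    names(sets) <- sprintf("set%02d", seq_len(n_sets))
    list(scores = ranked_scores(sc), sets = set_collection(sets))
  })
}

#' Synthetic planted-enrichment instance
#'
#' Like [make_null_instance()], but one designated set is genuinely enriched:
#' its members' scores are shifted upward by `shift` in every phenotype, on
#' top of `N(0, noise_sd^2)` noise. `shift = 0` degenerates to a null
#' instance. The returned `truth` record names the planted set so recovery
#' (does the planted set attain the top NES?) can be scored.
#'
#' @inheritParams make_null_instance
#' @param planted_set_index Which of the `n_sets` sets carries the effect.
#' @param shift Nonnegative effect size added to planted members' scores.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @return List with `scores`, `sets`, and `truth` (list with
#'   `planted_set`, `shift`, `noise_sd`).
#' @export
make_planted_instance <- function(L, n_sets, set_size_range = c(5L, 20L),
                                  planted_set_index = 1L, shift = 2,
                                  noise_sd = 1, n_phenotypes = 1L,
                                  seed = NULL) {
  if (shift < 0) csea_stop("`shift` must be >= 0", "csea_contract_error")
  if (noise_sd <= 0) csea_stop("`noise_sd` must be > 0", "csea_contract_error")
  planted_set_index <- as.integer(planted_set_index)
  if (planted_set_index < 1 || planted_set_index > n_sets)
    csea_stop("`planted_set_index` out of range", "csea_contract_error")
  inst <- with_seed(seed, {
    base <- make_null_instance(L, n_sets, set_size_range,
                               n_phenotypes = n_phenotypes, seed = NULL)
    sc <- unclass(base$scores) * noise_sd
    planted <- base$sets[[planted_set_index]]
    sc[planted, ] <- sc[planted, ] + shift
    list(scores = ranked_scores(sc), sets = base$sets)
  })
  inst$truth <- list(planted_set = names(inst$sets)[planted_set_index],
                     shift = shift, noise_sd = noise_sd)
  inst
}

#' Coefficient cubes for multitask multilevel models
#'
#' A `coefficient_cube` is a dense 3-D numeric array indexed
#' (level, feature, task) with mandatory unique dimension labels — the shape
#' of the coefficient output of a multitask multilevel regression with T
#' sample levels (e.g. cancer types), p features (e.g. genes) and m tasks
#' (e.g. drugs).
#'
#' @param values Numeric 3-D array, dimensions (T, p, m).
#' @param level_ids,feature_ids,task_ids Unique label vectors matching the
#'   array extents; taken from `dimnames(values)` when omitted.
#' @return A `coefficient_cube`.
#' @export
coefficient_cube <- function(values, level_ids = NULL, feature_ids = NULL,
                             task_ids = NULL) {
  if (!is.array(values) || length(dim(values)) != 3 || !is.numeric(values))
    csea_stop("`values` must be a numeric 3-D array (level, feature, task)",
              "csea_validation_error")
  dn <- dimnames(values)
  if (is.null(level_ids))   level_ids   <- dn[[1]]
  if (is.null(feature_ids)) feature_ids <- dn[[2]]
  if (is.null(task_ids))    task_ids    <- dn[[3]]
  ids <- list(level_ids, feature_ids, task_ids)
  for (a in 1:3) {
    if (is.null(ids[[a]]))
      csea_stop("all three axes need labels (level_ids, feature_ids, task_ids)",
                "csea_validation_error")
    if (length(ids[[a]]) != dim(values)[a] || anyDuplicated(ids[[a]]))
      csea_stop("axis labels must be unique and match the array extents",
                "csea_validation_error")
  }
  if (any(!is.finite(values)))
    csea_stop("cube values must be finite", "csea_validation_error")
  dimnames(values) <- lapply(ids, as.character)
  structure(values, class = c("coefficient_cube", "array"))
}

#' @export
print.coefficient_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<coefficient_cube> %d level(s) x %d feature(s) x %d task(s); %d nonzero\n",
              d[1], d[2], d[3], sum(x != 0)))
  invisible(x)
}

#' Random sparse coefficient cube
#'
#' Each entry is nonzero independently with probability `density`, with
#' `N(0, 1)` values — emulating the exact zeros of a sparse (lasso-type)
#' multitask multilevel estimator.
#'
#' @param T_levels,p,m Extents of the level, feature and task axes.
#' @param density Probability an entry is nonzero, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [coefficient_cube()].
#' @export
make_sparse_cube <- function(T_levels, p, m, density = 0.1, seed = NULL) {
  if (density < 0 || density > 1)
    csea_stop("`density` must lie in [0, 1]", "csea_contract_error")
  T_levels <- as.integer(T_levels); p <- as.integer(p); m <- as.integer(m)
  if (min(T_levels, p, m) < 1)
    csea_stop("all extents must be >= 1", "csea_contract_error")
  with_seed(seed, {
    n <- T_levels * p * m
    v <- rnorm(n) * (stats::runif(n) < density)
    a <- array(v, dim = c(T_levels, p, m),
               dimnames = list(paste0("level", seq_len(T_levels)),
                               sprintf("feat%03d", seq_len(p)),
                               paste0("task", seq_len(m))))
    coefficient_cube(a)
  })
}
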