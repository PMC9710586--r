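make_separated_instance <- function(L = 30, k = 5, n_decoys = 2, seed = 5) {
  # one set occupying exactly the top-k scores, plus random decoys
  set.seed(seed)
  feats <- sprintf("g%02d", seq_len(L))
  s <- sort(rnorm(L))
  names(s) <- feats       # feats[L] has the largest score
  sets <- c(list(top = feats[(L - k + 1):L]),
            lapply(seq_len(n_decoys), function(i) sample(feats, k)))
  names(sets) <- c("top", paste0("decoy", seq_len(n_decoys)))
  list(scores = ranked_scores(s), sets = set_collection(sets))
}

test_that("a perfectly separated set attains ES = 1 and the minimal p-value", {
  inst <- make_separated_instance()
  res <- csea(inst$scores, inst$sets,
              csea_config(alpha = 0, n_perm = 99, seed = 2))
  top <- res[res$set_id == "top", ]
  expect_equal(top$es, 1)
  expect_equal(top$p_value, 1 / 100)  # no random pseudo-set also separates
  expect_gt(top$nes, 1)
  expect_equal(nrow(res), 3)
})

test_that("results are deterministic and ordered by phenotype then NES", {
  inst <- make_null_instance(L = 80, n_sets = 6, set_size_range = c(5, 15),
                             n_phenotypes = 2, seed = 9)
  cfg <- csea_config(n_perm = 50, seed = 4)
  r1 <- csea(inst$scores, inst$sets, cfg)
  r2 <- csea(inst$scores, inst$sets, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  for (ph in unique(r1$phenotype_id)) {
    nes <- r1$nes[r1$phenotype_id == ph]
    expect_true(all(diff(nes) <= 0))
  }
  # joint adjustment across all (set, phenotype) pairs
  expect_equal(r1$p_adjusted[order(r1$set_id, r1$phenotype_id)],
               adjust_pvalues(r1$p_value, "benjamini_hochberg")[
                 order(r1$set_id, r1$phenotype_id)])
})

test_that("duplicated phenotype columns give identical enrichment scores", {
  set.seed(13)
  feats <- sprintf("g%02d", 1:40)
  col <- rnorm(40)
  m <- cbind(ph1 = col, ph2 = col)
  rownames(m) <- feats
  sets <- set_collection(list(S1 = feats[1:8], S2 = feats[30:40]))
  res <- csea(ranked_scores(m), sets, csea_config(n_perm = 30, seed = 1))
  wide <- split(res, res$phenotype_id)
  for (cn in c("es", "set_size", "which_max", "direction")) {
    a <- wide$ph1[order(wide$ph1$set_id), cn]
    b <- wide$ph2[order(wide$ph2$set_id), cn]
    expect_identical(a, b)
  }
})

test_that("each phenotype has its own RNG stream off the master seed", {
  inst <- make_null_instance(L = 60, n_sets = 4, set_size_range = c(5, 10),
                             n_phenotypes = 2, seed = 17)
  cfg <- csea_config(n_perm = 40, seed = 8)
  both <- csea(inst$scores, inst$sets, cfg)
  solo <- csea(ranked_scores(unclass(inst$scores)[, 1, drop = FALSE]),
               inst$sets, cfg)
  a <- both[both$phenotype_id == "phenotype1", ]
  expect_equal(a$p_value[order(a$set_id)], solo$p_value[order(solo$set_id)])
  expect_equal(a$nes[order(a$set_id)], solo$nes[order(solo$set_id)])
})

test_that("within one set-size stratum larger ES never has larger p-value", {
  inst <- make_null_instance(L = 100, n_sets = 12, set_size_range = c(8, 8),
                             seed = 23)
  res <- csea(inst$scores, inst$sets, csea_config(n_perm = 99, seed = 3))
  o <- order(res$es)
  expect_true(all(diff(res$p_value[o]) <= 0))
})

test_that("unknown members and undersized sets follow the configured policy", {
  set.seed(29)
  feats <- sprintf("g%02d", 1:20)
  rs <- ranked_scores(stats::setNames(rnorm(20), feats))
  sets <- list(ok = feats[1:5], ghost = c(feats[1:4], "nope"))
  expect_error(csea(rs, sets, csea_config(n_perm = 10, seed = 1)),
               "nope", class = "csea_unknown_feature_error")
  res <- suppressWarnings(
    csea(rs, sets, csea_config(n_perm = 10, seed = 1,
                               unknown_feature_policy = "drop_with_warning")))
  expect_setequal(unique(res$set_id), c("ok", "ghost"))
  expect_equal(res$set_size[res$set_id == "ghost"], 4L)

  expect_error(
    suppressWarnings(
      csea(rs, list(tiny = feats[1]), csea_config(n_perm = 10))),
    class = "csea_nothing_to_test_error")
})

test_that("planted enrichment is recovered on a single strong instance", {
  inst <- make_planted_instance(L = 200, n_sets = 10,
                                set_size_range = c(20, 20), shift = 3,
                                noise_sd = 1, seed = 37)
  # n_perm = 500 puts the attainable p floor (1/501) well below the BH
  # cutoff for 10 simultaneous sets
  res <- csea(inst$scores, inst$sets, csea_config(n_perm = 500, seed = 37))
  expect_equal(res$set_id[which.max(res$nes)], inst$truth$planted_set)
  expect_true(res$significant[res$set_id == inst$truth$planted_set])
})
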