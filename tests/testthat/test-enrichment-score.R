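test_that("weighted ECDFs match hand-computed values", {
  e0 <- weighted_ecdfs(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), alpha = 0)
  expect_equal(e0$F_hit, c(0, 0, 0.5, 1))
  expect_equal(e0$F_miss, c(0.5, 1, 1, 1))

  # alpha = 1: hit weights 3 and 4, denominator 7
  e1 <- weighted_ecdfs(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), alpha = 1,
                       mode = "classic")
  expect_equal(e1$F_hit, c(0, 0, 3 / 7, 1))
  expect_equal(e1$F_miss, c(0.5, 1, 1, 1))

  # as-printed dialect keeps the weighted numerator over L - L_k
  ap <- weighted_ecdfs(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), alpha = 1,
                       mode = "as_printed")
  expect_equal(ap$F_miss, c(1 / 2, 3 / 2, 3 / 2, 3 / 2))
})

test_that("the two miss-curve dialects coincide at alpha = 0", {
  set.seed(21)
  for (rep in 1:25) {
    L <- sample(5:40, 1)
    s <- sort(rnorm(L))
    memb <- seq_len(L) %in% sample(L, sample(2:(L - 2), 1))
    a <- weighted_ecdfs(s, memb, alpha = 0, mode = "classic")
    b <- weighted_ecdfs(s, memb, alpha = 0, mode = "as_printed")
    expect_identical(a, b)
  }
})

test_that("degenerate memberships and vanishing weights are rejected", {
  expect_error(weighted_ecdfs(1:4, rep(TRUE, 4), alpha = 0),
               class = "csea_degenerate_set_error")
  expect_error(weighted_ecdfs(1:4, rep(FALSE, 4), alpha = 0),
               class = "csea_degenerate_set_error")
  expect_error(weighted_ecdfs(c(0, 0, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                              alpha = 1),
               class = "csea_degenerate_weight_error")
})

test_that("enrichment_score is the largest absolute gap, first on ties", {
  es <- enrichment_score(c(0, 0, 0.5, 1), c(0.5, 1, 1, 1))
  expect_equal(as.numeric(es), 1)
  expect_equal(attr(es, "which_max"), 2)
  expect_equal(attr(es, "direction"), -1)

  same <- c(0.2, 0.5, 1)
  expect_equal(as.numeric(enrichment_score(same, same)), 0)
  expect_error(enrichment_score(c(0, 1), c(0, 0.5, 1)),
               class = "csea_contract_error")
})

test_that("alpha = 0 score equals the brute-force two-sample KS statistic", {
  set.seed(31)
  for (rep in 1:60) {
    L <- sample(4:50, 1)
    scores <- rnorm(L)
    k <- sample(1:(L - 1), 1)
    members <- sample(L, k)
    ord <- rank_features(scores)
    memb <- ord %in% members
    e <- weighted_ecdfs(scores[ord], memb, alpha = 0)
    expect_equal(as.numeric(enrichment_score(e$F_hit, e$F_miss)),
                 oracle_ks(scores[members], scores[-members]),
                 tolerance = 1e-12)
  }
})

test_that("classic-mode score is bounded by 1, attained only at perfect separation", {
  set.seed(41)
  for (rep in 1:40) {
    L <- sample(6:60, 1)
    s <- sort(rnorm(L))
    k <- sample(2:(L - 2), 1)
    idx <- sample(L, k)
    e <- weighted_ecdfs(s, seq_len(L) %in% idx, alpha = runif(1, 0, 2))
    v <- as.numeric(enrichment_score(e$F_hit, e$F_miss))
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    separated <- all(idx <= k) || all(idx > L - k)
    expect_equal(v == 1, separated)
  }
})

test_that("classic-mode score is invariant to positive rescaling of scores", {
  set.seed(51)
  for (alpha in c(0, 0.5, 1, 2)) {
    L <- 30
    s <- sort(rnorm(L))
    memb <- seq_len(L) %in% sample(L, 7)
    base <- weighted_ecdfs(s, memb, alpha = alpha)
    for (c0 in c(0.01, 3, 1e4)) {
      sc <- weighted_ecdfs(s * c0, memb, alpha = alpha)
      expect_equal(as.numeric(enrichment_score(sc$F_hit, sc$F_miss)),
                   as.numeric(enrichment_score(base$F_hit, base$F_miss)),
                   tolerance = 1e-12)
    }
  }
})

test_that("classic weighted score matches fgsea's running-sum statistic", {
  # fgsea traverses the list in descending order; the sup of the absolute
  # running-sum gap is traversal-invariant, so magnitudes must agree.
  set.seed(61)
  for (rep in 1:20) {
    L <- sample(20:80, 1)
    stats <- sort(rnorm(L), decreasing = TRUE)
    names(stats) <- paste0("g", seq_len(L))
    k <- sample(3:10, 1)
    sel <- sample(L, k)
    alpha <- sample(c(0, 1, 2), 1)
    ref <- abs(fgsea::calcGseaStat(stats, selectedStats = sel,
                                   gseaParam = alpha))
    asc <- rev(stats)
    memb <- seq_len(L) %in% (L + 1 - sel)
    e <- weighted_ecdfs(asc, memb, alpha = alpha, mode = "classic")
    expect_equal(as.numeric(enrichment_score(e$F_hit, e$F_miss)), ref,
                 tolerance = 1e-10)
  }
})
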