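# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: plain definitional computations.

# Two-sample Kolmogorov-Smirnov statistic by brute-force threshold scan:
# sup over all observed thresholds of |ECDF_in(t) - ECDF_out(t)|.
oracle_ks <- function(in_scores, out_scores) {
  th <- sort(unique(c(in_scores, out_scores)))
  max(vapply(th, function(t) {
    abs(mean(in_scores <= t) - mean(out_scores <= t))
  }, numeric(1)))
}

# Benjamini-Hochberg step-up, written from the textbook definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# selections of size `sel` from `N` items of which `K` are set members.
oracle_hyper_enum <- function(hits, sel, K, N) {
  sels <- utils::combn(N, sel)
  members <- seq_len(K)
  mean(apply(sels, 2, function(s) sum(s %in% members) >= hits))
}

# Classic (alpha = 0) enrichment score straight from its definition, for an
# arbitrary membership over an ordered list.
oracle_es_alpha0 <- function(L, hit_idx) {
  hit <- seq_len(L) %in% hit_idx
  F_hit <- cumsum(hit) / sum(hit)
  F_miss <- cumsum(!hit) / sum(!hit)
  max(abs(F_hit - F_miss))
}

# Mean null enrichment score by exhaustive enumeration of every subset of
# size k (columns of combn) against one ordered score vector.
oracle_exact_null_mean <- function(ordered_scores, k, alpha = 0,
                                   mode = "classic") {
  L <- length(ordered_scores)
  w <- abs(ordered_scores)^alpha
  subsets <- utils::combn(L, k)
  mean(apply(subsets, 2, function(idx) {
    hit <- seq_len(L) %in% idx
    F_hit <- cumsum(w * hit) / sum(w * hit)
    F_miss <- if (mode == "classic") cumsum(!hit) / (L - k)
              else cumsum(w * !hit) / (L - k)
    max(abs(F_hit - F_miss))
  }))
}
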