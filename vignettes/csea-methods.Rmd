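---
title: "Custom set enrichment analysis: model, choices and validation"
author: "csea package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Custom set enrichment analysis: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csea)
```

## The enrichment model

`csea()` asks, for each user-defined set $G_k$ and each phenotype, whether
the set's members concentrate at one end of a ranked feature list. Features
are indexed by ascending rank metric $s_1 \le \dots \le s_L$. Two running
curves are compared: the in-set curve, which accumulates weight
$|s_t|^\alpha$ over member positions and is normalized by the total member
weight, and the out-of-set curve over the complement $\bar G_k$. The
enrichment score is the supremum of their absolute gap,

$$S_k = \sup_{1 \le i \le L} \left| F_i^{G_k} - F_i^{\bar G_k} \right|,$$

a weighted two-sample Kolmogorov–Smirnov statistic. Because it is a
supremum of absolute deviations, $S_k \ge 0$ always and the test is
two-sided: enrichment at the top and at the bottom of the ranking score
alike. The position of the supremum and the sign of the gap there are
returned as diagnostics (`which_max`, `direction`); they identify where and
in which direction the separation happens but do not enter the statistic.
The supremum of the absolute gap is invariant to traversing the list in
either direction, while those diagnostics are not — hence the package fixes
ascending traversal and documents it.

### The two out-of-set curve dialects

Published formulations of the statistic differ in the out-of-set curve.
The classic convention (used by the mainstream gene-set enrichment
literature, and this package's default, `miss_ecdf_mode = "classic"`) takes
the plain unweighted ECDF of the complement: each non-member contributes
$1/(L - L_k)$, so the curve is a proper CDF ending at 1 and
$0 \le S_k \le 1$, with $S_k = 1$ exactly when the members perfectly
separate from the non-members. A second form in circulation keeps the
weighted numerator $\sum_{t \le i} |s_t|^\alpha \, 1\{t \in \bar G_k\}$
over the *unweighted* denominator $L - L_k$; for $\alpha > 0$ that curve
need not end at 1 and the score can exceed 1. Whether that form is
intentional or a transcription slip of the classic convention is not
decidable from the descriptions alone, so both are implemented
(`miss_ecdf_mode = "as_printed"` preserves the literal form) and neither is
asserted as "correct". At $\alpha = 0$ they coincide. The default is
classic because its bounds and calibration properties are the ones users
expect of a KS-type score.

### Permutation null, p-values, NES

A standalone ranked list carries no sample-level data to permute, so the
null is a *set permutation*: `n_perm` pseudo-sets of size $L_k$ drawn
uniformly without replacement from the list positions, each scored on the
same ranking. The empirical p-value uses the add-one form
$(1 + \#\{S^{null} \ge S_k\})/(1 + n_{perm})$ — ties count toward the
tail, the smallest attainable value is $1/(n_{perm}+1)$, never zero. The
normalized enrichment score divides the observed score by its null mean,
$NES_k = S_k / \overline{S^{null}_k}$, which removes the strong set-size
dependence of the raw score. Normalization is per set, against the set's
own null; since the null depends only on $L_k$, sets of equal size within
one phenotype share one null draw — this is both faster and guarantees
that, within such a stratum, a larger score never receives a larger
p-value.

Multiplicity correction pools every (set, phenotype) pair into a single
family (Benjamini–Hochberg by default; Bonferroni, Holm and none are
available), matching how a set-by-phenotype summary grid is read: all cells
at once. Significance in the result table and the plot is
`p_adjusted < sig_level`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | weight exponent on \|score\| (dimensionless); 0 = classic KS, 1 = customary weighted form |
| `n_perm` | 100 | permutation count; p floor is 1/(n_perm+1), so raise it when many sets must clear an adjusted threshold |
| `miss_ecdf_mode` | `classic` | out-of-set curve dialect (above) |
| `seed` | `NULL` | master seed; each phenotype gets an independent derived stream, so adding a phenotype never perturbs another's p-values |
| `sig_level` | 0.05 | level applied to adjusted p-values |
| `correction_method` | BH | family over all (set, phenotype) pairs |
| `min_set_size` | 2 | smaller sets are dropped with a warning; sets covering the whole universe are rejected (empty complement) |
| `unknown_feature_policy` | `error` | members absent from the ranked list abort by default; `drop_with_warning` for practicality |

Degenerate inputs are refused loudly rather than propagated as NaN: an
all-member or all-non-member "set", and the case where every member score
is exactly 0 with $\alpha > 0$ (the in-set weight normalizer vanishes).
Ties in scores keep input order (stable sort); ties in the supremum resolve
to the smallest position.

## Over-representation for unranked lists

When the input is a selection rather than a ranking,
`overrepresentation_test()` gives the hypergeometric upper tail
$P(X \ge h)$ for $h$ set members in a selection of size $n$ from a
universe of $N$ with $K$ members — the one-sided Fisher test for a
2×2 table with fixed margins.

## The Sankey component

`build_sankey_graph()` consumes a dense array of regression coefficients
indexed (level $t = 1 \dots T$, feature $j = 1 \dots p$, task
$q = 1 \dots m$) — the coefficient output of a multitask multilevel model.
Axis order is fixed and labels are mandatory, so files are validated by
declared role, not position alone. Every entry with $|\beta_{tjq}|$ above
the threshold emits a level→feature and a feature→task link of weight
$|\beta_{tjq}|$; parallel links merge by summation (legibility), with the
sign of the summed raw coefficients kept as an attribute for coloring. The
threshold defaults to 0 — strict nonzero selection, the natural choice for
lasso-type estimators that produce exact zeros; dense estimators can raise
it. By construction each feature node conserves flow (level-side total =
task-side total = summed magnitude of its surviving entries), which the
tests verify independently.

A feature's *intersection pattern* is the pair (tasks with any surviving
entry, levels with any surviving entry); across features at most
$(2^m - 1)(2^T - 1)$ distinct patterns exist. `render_sankey()` writes a
self-contained HTML document — an embedded SVG renderer with no external
assets, so it opens offline — ordered level → feature → task left to right
(a presentation choice only), plus a JSON sidecar that round-trips
losslessly back into the graph object; the sidecar, not the HTML, is the
machine-readable artifact.

## Synthetic data: what it emulates, what it does not

The generators exist so that every statistical property of the method can
be checked against known ground truth.

* `make_null_instance()` draws i.i.d. standard normal scores and sets
  sampled independently of the scores — the exchangeable null under which
  p-values must be uniform on the achievable grid.
* `make_planted_instance()` adds a shift to one set's members' scores
  (`shift` in units of `noise_sd`), a single-effect alternative for
  recovery power checks. Its default conditions for the headline recovery
  check are `shift = 3`, `noise_sd = 1`, `L = 200`, set size 20 with 19
  decoy sets.
* `make_sparse_cube()` sets each coefficient nonzero independently with
  probability `density`, values standard normal — emulating the exact-zero
  sparsity pattern of lasso-type output.

The Gaussian score model is chosen for analytic transparency; the
enrichment statistic is rank-driven at $\alpha = 0$ and
magnitude-weighted at $\alpha > 0$, but its null calibration does not
depend on the marginal law, so passing these checks supports validity on
real rankings. What the generators deliberately do **not** emulate:
correlated scores (co-regulated genes, drugs with shared mechanism),
heavy-tailed or bimodal rank metrics, overlapping set structure beyond
random collisions, and real drug-screen response scales. Uniform p-values
under independence do not guarantee calibration under strong inter-feature
correlation — the usual caveat for all set-permutation enrichment nulls.

## Numerical and design choices

* Ascending rank indexing ($s_1$ smallest); stable tie-break by input
  order.
* Add-one p-values (never zero), ties counted as $\ge$.
* One RNG stream per phenotype derived from the master seed; all
  generators and `csea()` are bit-deterministic given a seed, and seeded
  runs written to disk are byte-identical.
* Identical phenotype columns therefore get identical scores but
  independently drawn nulls — determinism is per stream, not shared
  across phenotype positions.
* Result tables are written with full double precision (`%.17g`), so
  writer/reader pairs are exact inverses.
* Null draws are shared across equal-size sets within a phenotype; the
  normalization is per set (its own null), not per size stratum of some
  other set.

## Validation conditions and limitations

The test suite and `scripts/acceptance.R` validate, at these problem
sizes: exact equality of the $\alpha = 0$ score with a brute-force KS
threshold scan (200 instances, $L \le 50$); the perfect-separation bound
(100 constructions); p-value uniformity under the null via chi-square
goodness of fit on the achievable grid (500 instances, $L = 100$,
$L_k = 10$, `n_perm = 199`, $\alpha = 1$, 10 bins, 1% level); mean NES of
null-drawn scores within 3 Monte-Carlo SE of 1 (500 replicates);
planted-set recovery (top NES in $\ge 90\%$ of 100 replicates at the
planted conditions above); the sampled permutation mean against exhaustive
enumeration of all $\binom{20}{5} = 15{,}504$ subsets; Sankey flow
conservation and the pattern-count formula against double-powerset
enumeration for $m, T \le 5$; and byte-identical seeded reruns. An
independent cross-check compares the classic weighted score against the
running-sum statistic of the `fgsea` package on random instances.

Known limitations: no sample-level (expression-matrix) permutation scheme;
no leading-edge subset extraction; no running-sum trajectory plots; set
overlap is not corrected for (overlapping decoys can ride along with a
true signal, as the README example shows); and the `as_printed` dialect's
score is unbounded above, so its NES should be compared only within one
dialect.
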