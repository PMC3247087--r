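---
title: "Detecting weak marginal, strong bivariate interactions with QDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting weak marginal, strong bivariate interactions with QDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdadetect)
```

## The problem

In two-class expression studies (tumour versus normal tissue, treated
versus control cells) the number of features `p` dwarfs the number of
samples `n`. Univariate screens and sequential feature-selection methods
find genes that are individually differentially expressed — but they
systematically discard *weak marginal / strong bivariate* interactions:
pairs of genes whose individual class-conditional distributions overlap
almost completely, while their joint distribution separates the classes
cleanly. Two obstacles stand in the way of finding such pairs directly:

1. **Combinatorics.** Scoring every pair of `p = 2000` genes needs
   `p(p-1)/2 = 1999000` classifier fits.
2. **Peaking.** Any classifier trained on a feature chunk containing the
   pair plus many uninformative features degrades as the chunk grows; at
   a fixed sample size the signal eventually drowns in the noise.

`qdadetect` addresses both with a two-stage blockwise search driven by
the cross-validated error of a quadratic discriminant analysis (QDA)
classifier.

## The classifier

Binary QDA models each class as a multivariate Gaussian
`N(mu_c, Sigma_c)` with prior `pi_c` and predicts the class with larger
posterior; the decision boundary is the hyperquadric on which

```
log pi_1 - (1/2) log det Sigma_1 - (1/2) (x - mu_1)' Sigma_1^{-1} (x - mu_1)
```

equals the analogous class-0 expression. Because the boundary shape is
governed by the difference of the inverse covariances, QDA traces
elliptical, hyperbolic, parabolic and linear separations — rich enough to
catch interaction geometries (XOR-like, circular, band-shaped) that
correlation- or rank-based pair scores are blind to, yet cheap enough to
fit tens of thousands of times. `fit_qda()` plugs in the sample means,
the sample covariances (denominator `n_c - 1`) and the priors
(class proportions by default; `"balanced"` and explicit pairs are
available, which matters for unbalanced designs such as 40 tumours
against 22 normals).

Numerical choices, fixed and documented:

* **Ridge.** A ridge `1e-6 * trace(S_c)/p` is always added to each
  covariance diagonal, so folds that leave `n_c <= p` training samples
  keep a positive-definite covariance. Increasing the ridge can never
  break positive-definiteness. The value is small enough that it leaves
  well-conditioned fits unchanged to many digits.
* **Tie-break.** A discriminant score of exactly zero predicts class 0.
* **Error estimate.** `cv_error()` uses stratified 10-fold
  cross-validation — stratification guarantees both classes appear in
  every training fold even when one class is small — and pools the
  misclassified counts over folds (identical to averaging per-fold rates
  when fold sizes are equal). The fold partition is a deterministic
  function of `(y, k, seed)` alone, *not* of the feature columns, so all
  feature subsets scored within one search share identical folds: the
  ranking compares errors under a paired design.

The fold loop is implemented in compiled code (RcppArmadillo) because a
single search evaluates on the order of 10^4 plug-in fits; a pure-R
reference implementation (`fit_qda()` / `qda_predict()`) defines the
semantics and the test suite asserts exact agreement between the two
routes, as well as agreement with the Bayes rule when population
parameters are supplied via `qda_model()`.

## The synthetic scenarios

Four seeded generators (`scenario_spec()` / `simulate_scenario()`)
produce planted two-feature patterns, each marginally weak:

* **linear** — both classes bivariate normal, means `(0,0)` and
  `(-1,1)`, shared covariance `[[1, .9], [.9, 1]]`. The unit variances
  keep each marginal overlapping (one SD of mean shift per axis) while
  the strong positive correlation makes the shift nearly orthogonal to
  the principal noise axis, so the pair separates cleanly.
* **xor** — class 0 uniform on the two quadrants of `[-1,1]^2` where the
  coordinates share a sign, class 1 where they differ.
* **circular** — standard bivariate normal; label 0 iff the squared
  radius is at most `r0sq`, label 1 iff above `r1sq`. Both thresholds
  default to the chi-squared(2) median (≈ 1.386), balancing the classes
  in expectation with no gap; setting `r0sq < r1sq` opens one.
* **vshape** — `x1` uniform on `[-1,1]`; class 0 has `x2` uniform on
  `[|x1|, |x1|+0.3]`, class 1 on the disjoint band
  `[|x1|+0.5, |x1|+0.8]`.

These constants are the package's defaults, chosen once so that at
`n0 = n1 = 40` each marginal's univariate CV error sits near its Bayes
error (0.25–0.5 across the scenarios) while the pair attains a far lower
error; all are parameters. Two caveats the tests make explicit: in the
V-shaped pattern the upward shift of the class-1 band leaves the second
component with some marginal signal of its own (its univariate error is
markedly below chance — visible as a low diagonal entry in the heat
matrix), and the plug-in quadratic boundary captures the V-channel only
approximately, so the V pair's bivariate error (≈ 0.24) is well above
that of the other three patterns (≤ 0.08). Detection guarantees are
therefore stated for the linear, XOR and circular patterns.

`add_noise_features()` embeds a pattern in i.i.d. standard-normal noise
columns drawn under a separate seed (so enlarging the embedding never
perturbs the signal draw), and `simulate_noise_only()` produces the
matching pure-noise null. What the generators deliberately do *not*
emulate: correlated noise, heavy-tailed or discrete expression
distributions, batch structure, missing values. Passing tests on these
generators show the search recovers planted geometric interactions at
the stated dimensions and sample sizes — not that real arrays satisfy
the Gaussian noise model.

## Peaking, and how it sets the block size

`peaking_curve()` traces mean CV error against total dimension: with 80
samples the error on the linear pattern climbs from ≈ 0.02 at `p = 2`
toward chance as noise dimensions are added. `overlap_experiment()`
quantifies when the classifier can still tell a signal-bearing chunk
from pure noise: for each `p` it builds `B` signal and `B` noise
datasets (replicate `b` seeds both arms with `root_seed + b`, pairing
them), scores each by CV error, and summarizes the separation of the two
error populations by `Phi(-Delta/2)`, where `Delta` is the mean gap
standardized by the pooled SD (the univariate Mahalanobis distance; with
equal arm sizes pooled and simple-average SDs coincide). Under
equal-covariance Gaussian assumptions this is the error of the linear
discriminant separating the two populations — 0.5 means
indistinguishable.

Across all four scenarios the overlap stays below 5% for chunk sizes
under 10 and grows with `p`. That threshold `p* = 10` is the
*peaking-resistance threshold*: the search may fit QDA on any feature
chunk of size up to `p*` and still trust a low error to indicate signal.

## The two-stage search

`detect_interactions()`:

1. **Blockwise ranking.** `partition_blocks()` tiles the `p` features
   into `ceiling(p/bsize)` blocks of `bsize` consecutive columns (the
   remainder forms a smaller last block; an optional seeded shuffle
   randomizes the assignment as a robustness check). Every unordered
   pair of blocks is scored by the CV error of QDA on the union of their
   features — at most `2*bsize` columns, and the configuration is
   rejected at construction unless `2*bsize <= p*`. With `p = 2000` and
   `bsize = 5` this is 79800 fits instead of the exhaustive 1999000.
   A matching whose union contains a planted pair scores far below the
   ≈ 0.5 of pure-noise matchings.
2. **Heat-matrix refinement.** The `top_m` matchings (default 6, a
   practical inspection depth for real data) are expanded:
   `pairwise_heatmatrix()` scores *every* pair within the union of each
   matching's blocks — within-block pairs included, since the planted
   pair may sit inside one block — and puts univariate errors on the
   diagonal, which exposes "not so weak" single features. All scored
   pairs are pooled, de-duplicated and returned sorted by error with
   lexicographic tie-breaks, so the result is a total order and reruns
   are bit-identical. No numeric hot-spot threshold is imposed; callers
   (and the CLI, which prints the top 10) cut the list themselves.

On the synthetic experiment — a planted pair plus 198 noise features, so
the signal is 1% of a 200-dimensional space, `bsize = 5`,
`n0 = n1 = 40` — the planted pair ranks first in ≥ 99 of 100 seeded
runs for the linear, XOR and circular patterns (the test suite asserts
≥ 90).

For real data the recommended recipe is: log-transform and standardize
(`preprocess_expression()`, natural log; standardization is per feature),
remove a user-supplied outlier list (1-based sample indices), screen out
the strongest marginal features first — `screen_by_importance()` applies
the cut given any external importance vector, e.g. a random-forest
mean-decrease-Gini ranking, since strong marginals are exactly what this
search is not for — and drop exactly duplicated columns
(`drop_duplicate_features()`). The published colon-cancer analysis
(62 samples, 2000 genes, 100 screened, 1891 features retained) is
reproducible with this pipeline but requires downloading that dataset;
it is documented in the README as an optional integration check, not
part of the test suite.

## Comparison scores

`tsp_score()` (top scoring pair) is the absolute between-class
difference of `P(x_i < x_j)`, with exact ties contributing 1/2
(midrank convention — tie handling is a documented package choice);
it is rank-based and invariant under joint strictly monotone
transformations. `corscor_score()` is the absolute difference of the
within-class Pearson correlations, on `[0, 2]` — the gap/substitution
form, consistent with published values exceeding 1; the on/off variant
is out of scope. Both assume a specific interaction shape (an order
switch, a correlation change); the QDA search does not, which is why it
can surface, e.g., XOR-like pairs both scores miss.

## Problem sizes and determinism

The shipped experiments use `n0 = n1 = 40`, `B = 100` replicates for the
overlap study, dimension grids up to `p = 100` for the peaking curve and
`p = 200` for the synthetic detection experiment — the same sizes as the
reference study conditions; the whole suite runs in a few minutes on one
CPU because the fold loop is compiled. Every stochastic function takes
an explicit seed and derives sub-streams deterministically
(Lehmer-style mixing, always below 2^31), so every reported number is
reproducible bit for bit from its seed.

## Known limitations

* Binary classification only; the multi-class extension is future work.
* Stage 2 inspects only the top `top_m` matchings: a pair split across
  two blocks that never co-occur in a top matching is missed. The seeded
  shuffle partitions differently and can recover such splits.
* The block partition is column-order dependent by default (documented;
  shuffle available).
* Importance-based screening and outlier detection are delegated to the
  caller; the package only applies the cuts.
* CV error at these sample sizes has granularity 1/80; ties among
  near-equal pairs are resolved lexicographically, not statistically.
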