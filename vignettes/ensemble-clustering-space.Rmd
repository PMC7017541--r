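---
title: "Classifying groups in an ensemble clustering space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying groups in an ensemble clustering space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecspace)
```

## The model

`ecspace` implements a transductive, group-based classifier for
partially labelled numeric data. Its premise is the cluster assumption:
points that repeatedly land in the same cluster are more alike than
their geometric distance suggests. Rather than engineering a distance,
the package *re-represents* every point by its clustering history.

Given a feature table whose rows are points (labelled set $D$,
unlabelled set $A$, pooled $E = D \cup A$), k-means is run once for
every $k = 2, \dots, nmc$ on all of $E$. Point $i$ becomes the
categorical vector $\hat{x}_i = (c_{2,i}, \dots, c_{nmc,i})$, where
$c_{k,i}$ is the cluster token the $k$-cluster run assigned to point
$i$. Stacking these vectors gives the $n \times (nmc-1)$ categorical
matrix `cMat`. A $k = 1$ column would be constant and carries no
information, so recording starts at $k = 2$.

Two points with identical rows were never separated by any run; they
collapse into a **group** and are classified as one unit:

* **unanimous** — every labelled member carries the same class; the
  group takes it, independent of any randomness;
* **majority** — labelled members disagree; one labelled member is drawn
  uniformly at random $r$ times and the group takes the majority class
  of the $r$ drawn labels (the draw count for a class with labelled
  share $p$ is Binomial$(r, p)$, so the assignment converges to the
  labelled majority as $r$ grows);
* **nearest-group** — no member is labelled; the group inherits the
  class of the labelled group with the highest representative
  similarity
  $\mathrm{sim}(\hat{x}, \hat{y}) = \frac{1}{m}\sum_{i=1}^{m}
  \mathbb{1}[c_i = v_i]$, with $m = nmc - 1$ the EC dimension (not the
  point count).

Grouping quality is summarised by the purity
$\mathrm{purity}(g) = \sum_j p_j^2$ over the class probabilities $p_j$
among a group's *labelled* members: 1 when pure, $1/\#\mathrm{classes}$
at the uniform floor. The grouping also measures redundancy: the
reduction ratio $s/n$ (groups over points) says how much smaller the
data become when EC-identical points merge.

The method is transductive by construction: unlabelled points shape the
clustering itself, so there is no out-of-sample `predict()` for unseen
points — new points require re-running the transform on the enlarged
pool. This is inherent to the method, not an implementation limit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nmc` | — (10–50 typical) | largest cluster count; EC dimension is `nmc - 1`. Larger `nmc` refines the grouping (group count is non-decreasing) and eventually isolates every point |
| `r` | 100 | random representative draws per mixed group; only affects groups whose labelled members disagree |
| `seed` | — | master seed; each EC column uses a seed derived from `(seed, k)`, so a transform at smaller `nmc` is a column prefix of one at larger `nmc` |
| `nstart` | 10 | k-means restarts per column; best total within-cluster sum of squares wins |
| `iter_max` | 300 | k-means iteration cap |
| `init` | `"plusplus"` | spread-out center seeding (each new center sampled proportional to squared distance from the nearest chosen one); `"random"` samples uniformly among distinct rows |
| `standardize` | `FALSE` | optional z-scoring before clustering; off by default because k-mer frequencies are already on a common scale |

## Numerical and design choices

* **Token canonicalization.** k-means numbers clusters arbitrarily, so
  each column's tokens are renumbered by order of first appearance
  (`c0`, `c1`, ...). Grouping is invariant to any within-column
  relabelling; canonicalization only makes output files stable.
* **`k` larger than the data.** The effective `k` is capped at the
  number of distinct feature rows (with a warning); empty clusters after
  convergence are tolerated — a column may hold fewer than `k` tokens.
* **Seed flow.** Every source of randomness (per-column k-means, the
  $r$ draws, train/test splits, the generator) descends from one master
  seed through an integer hash kept below $2^{31}$.
* **Ties.** Majority ties among the $r$ draws go to the
  lexicographically smallest class. Nearest-group ties go to the
  candidate with more labelled members, then the lowest group id. Both
  rules exist purely for reproducibility.
* **Draws are restricted to labelled members.** A drawn unlabelled
  member would carry no label; restricting the draw is what makes the
  repeated-draw procedure consistent with the three-case rule, and
  fully unlabelled groups are exactly the nearest-group case.
* **Undefined purity.** A group with no labelled member has no class
  probabilities; its purity is `NA`, never a number.
* **Scoring.** Sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$,
  accuracy $(TP+TN)/n$, F-measure as the precision–recall harmonic
  mean, Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with marginal-product
  expected agreement. Zero-denominator ratios are `NaN` with a warning.
  Multi-class inputs report accuracy and kappa only; the remaining
  columns are binary notions and are returned as `NA`.
* **Sweeps.** "Equal sample size" across iterations is implemented as
  stratified splitting: each class hides the same fraction of its
  labelled points, so class balance is preserved at every iteration.
* **Baselines.** The comparison harness pits the EC classifier against
  k-nearest neighbours, a Gini decision tree and a bagged forest on the
  original features (and the forest on the one-hot EC matrix). These are
  deliberately small reference implementations living in the package;
  they exist to anchor the comparison on synthetic data, not to compete
  with production learners.

## Sequence featurization

RNA precursor sequences (alphabet `{A, U, C, G}`; `T` accepted and
mapped to `U`) are represented by k-mer frequencies: the count of each
length-$k$ word among the $L - k + 1$ windows, divided by the sequence
length $L$. Both $L$ and $L-k+1$ normalizations exist in the
literature; this package uses $L$, so each k-block sums to
$(L-k+1)/L$. The default `k_set = 1:3` (84 features) is a documented
choice: the full published feature sets around this method mix k-mers
with distance and secondary-structure descriptors that are out of scope
here.

## What the synthetic generator does and does not emulate

`make_clustered_data()` draws isotropic unit-variance Gaussian clouds
with centres `separation` spread-units apart on a line, assigns each
cloud a class, copies a `duplicate_fraction` of rows exactly (so
EC-identical points exist by construction) and masks a
`unlabeled_fraction` of labels uniformly at random. It emulates the
cluster assumption in its cleanest form — well-separated, equal-spread,
class-aligned clouds with controllable redundancy.

It does **not** emulate real precursor data: no correlated k-mer
dimensions, no class-overlapping or anisotropic structure, no
label-dependent masking, no clade-level heterogeneity. A green
recovery test therefore establishes that the pipeline is correct and
self-consistent under its own assumptions, not that the published
accuracies on curated sequence collections are reproduced — those
depend on a 1000+-dimensional feature set that is out of scope.

## Known limitations

* The EC transform costs one k-means run per column and dominates run
  time; `nmc = 50` on thousands of points is minutes, not seconds.
* The grouping is exact-match only; near-duplicate grouping (similarity
  threshold below 1) is a documented non-goal.
* Only k-means drives the ensemble; other clusterers are an extension
  point, not an option.
* Printed worked-example matrices from the surrounding literature are
  fixtures, not regeneration targets: k-means initialisation there was
  never specified, so bit-exact regeneration is impossible in principle.
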