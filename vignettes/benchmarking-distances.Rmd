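---
title: "Benchmarking distance measures for gene expression clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking distance measures for gene expression clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedist)
```

## The problem

Clustering expression data always composes two choices: a clustering
method and a proximity measure between profiles. The method's bias is
widely discussed; the measure's bias much less, even though it decides
what "similar expression" means — similar magnitudes, similar linear
trend, similar rank order, or similar temporal shape. `genedist` makes
the measure a first-class experimental variable: fifteen measures behind
one interface, the clustering methods they are paired with in practice,
and evaluation scenarios that quantify how each pairing recovers known
structure or enriches for known gene sets.

## The fifteen measures

For profiles $x, y \in \mathbb{R}^n$:

* **Pearson (PE)** — product-moment correlation; invariant to positive
  affine maps, sensitive to outliers.
* **Spearman (SP)** — Pearson on fractional ranks; invariant to strictly
  monotone transforms. Ties get average ranks throughout the package.
* **Goodman-Kruskal (GK)** — $(P_+ - P_-)/(P_+ + P_-)$ over concordant
  and discordant pairs; neutral (tied) pairs are ignored entirely.
* **Kendall (KE)** — the tau-a form $(P_+ - P_-)/\binom{n}{2}$. This is
  a deliberate choice: the full-pair denominator means profiles with
  ties cannot reach $|KE| = 1$, and in particular $KE(x, x) < 1$ when
  $x$ has ties, so the distance matrix's diagonal is honestly positive
  there. The tie-corrected tau-b would hide this; we document it
  instead.
* **Rank-Magnitude (RM)** — the asymmetric coefficient
  $\hat r(x,y) = \frac{2\sum_i \mathrm{Rank}(x_i)\,y_i - \mathrm{maxrank} - \mathrm{minrank}}{\mathrm{maxrank} - \mathrm{minrank}}$
  (with $\mathrm{minrank}, \mathrm{maxrank}$ computed on $y$ sorted
  ascending), symmetrised as $(\hat r(x,y) + \hat r(y,x))/2$ so it
  captures ranks of one profile against magnitudes of the other, both
  ways.
* **Weighted Goodman-Kruskal (WGK)** — pairs weighted by signed
  range-normalised differences $w_{ij} = (x_i - x_j)/(\max x - \min x)$.
  The published piecewise definition is typographically ambiguous; we
  fix the interpretation as: concordant pairs contribute
  $\min(w^x/w^y, w^y/w^x) \in (0, 1]$, discordant pairs
  $\max(w^x/w^y, w^y/w^x) \in [-1, 0)$, double-tied pairs contribute 1,
  mixed tied/untied pairs 0, and the denominator counts both-untied
  plus double-tied pairs. This is the unique reading under which
  $WGK(x, x) = 1$ and the value stays in $[-1, 1]$; both properties are
  enforced by tests.
* **Cosine (COS)**, **Euclidean/Manhattan/Supremum (EUC/MAN/SUP)** —
  the traditional measures; the latter three are Minkowski with
  $\lambda = 2, 1, \infty$.
* **Jackknife (JK)** — $\min_{0 \le i \le n} PE^i(x, y)$ over the full
  profiles and every leave-one-feature-out copy; a guard against
  single-outlier false positives. Both a naive $O(n^2)$ path and an
  incremental sufficient-statistics path are implemented; they agree to
  $10^{-10}$ and the incremental one is used for long profiles.
* **STS** — the Euclidean norm of the difference between
  timestamp-normalised slope sequences; shift-invariant, interval-aware.
* **YS1 / YR1** — $\theta_1 A + \theta_2 M + \theta_3 S$ with $A$ the
  fraction of intervals with agreeing slope signs, $M \in \{0, 0.5, 1\}$
  scoring coincident extremum positions, and $S = (1 + \rho)/2$ a
  rescaled Spearman (YS1) or Pearson (YR1). Weights are fixed at
  $(1/4, 1/4, 1/2)$; estimating them per dataset is out of scope.
* **LSS** — the best probability-calibrated Spearman score over all
  equal-length window pairs (lengths $k$ from $min_k = n - 2$ to $n$,
  all offsets), capturing local and time-shifted agreement.

Correlations become distances via $d = 1 - r \in [0, 2]$; similarity
measures via $1 - s$.

### Numerical policies

* **Ties** get average (fractional) ranks wherever ranks are needed.
* **Degenerate inputs** (constant profiles, zero-norm vectors for
  cosine): the correlation/similarity is reported as 0 (distance 1)
  with a warning rather than an error, because real expression matrices
  contain flat profiles and a benchmark run must not abort on them.
* **Slope signs** in $A$ are compared exactly after floating-point
  evaluation, with no epsilon; synthetic fixtures use exact values and
  this is a documented limitation for data where slopes are
  numerically near zero.
* **Extremum ties** in $M$ resolve to the first occurrence.
* **Missing timestamps**: time-series measures error rather than
  silently assuming unit spacing; an explicit
  `unit_spacing_fallback = TRUE` opts in.

### The LSS window score

The original definition defers the window score to "the probability
associated with the correlation value". We implement
$S(k, \rho) = 1 - P(\rho_{null} \ge \rho)$ under the null of random
rank order: for $k \le 7$ the exact $k!$ permutation distribution of
Spearman's $\rho$ is enumerated (memoised per $k$); for larger $k$ the
$t$-approximation $t = \rho\sqrt{(k-2)/(1-\rho^2)}$ on $k - 2$ degrees
of freedom is used. Windows with internal ties are ranked fractionally
and scored against the tie-free null — an approximation we accept
because short expression series rarely tie within a window. With
$min_k = n$ and tie-free series, LSS reduces to the calibrated score of
plain Spearman on the full series (tested).

## Clustering

k-medoids is implemented in full because its exact protocol matters to
the benchmark: random initialisation, nearest-medoid assignment (ties
to the smaller medoid index), medoid update by minimum total
within-cluster distance (ties to the smaller object index), stopping
when memberships stabilise or after 100 iterations, 50 restarts with
restart $r$ seeded `seed + r`, best restart by objective (ties by
restart index), and empty clusters re-seeded with the object farthest
from its medoid. The objective is non-increasing within a run and the
returned run minimises it across restarts — both tested properties.

The three agglomerative linkages are standard steps and are delegated
to `stats::hclust`/`stats::cutree` behind the `linkage()` /
`cut_dendrogram()` surface. One consequence: merge ties are broken by
`hclust`'s internal (deterministic) rule rather than a lexicographic
pair rule of our own. Property tests draw continuous random matrices,
where ties have probability zero; single linkage is verified against an
independent minimum-spanning-tree oracle, and cuts are verified to be
nested refinements.

## Validation

The Adjusted Rand Index is computed from the contingency table (the
numerically stable route), with the pair-count form
$\frac{a - E}{M - E}$, $E = (a+b)(a+c)/\binom{n}{2}$, kept as a test
oracle; both forms agree to $10^{-12}$ on hundreds of random partition
pairs, and random relabelings centre on 0 (the chance correction).
When both partitions are trivial the denominator vanishes; we return 1
for identical partitions and 0 otherwise (a continuity convention).
Silhouette follows the $\frac{v - u}{\max(v, u)}$ definition with
singletons scoring 0, and is undefined (NA) outside $2 \le k \le n-1$;
those $k$ are simply not selectable.

Enrichment uses the one-sided hypergeometric tail
(`stats::phyper`) against the background of genes present in the
dataset (not the full annotation universe), retaining raw
$p \le 0.05$ — no multiple-testing correction by default, though
`p.adjust` methods can be switched on. Two enrichment lists are
compared by ascending sort, position-wise comparison over the shorter
length, and the signed statistic
$\log\frac{w_1 + 0.5}{w_2 + 0.5}$; the 0.5 pseudocount keeps the score
defined and antisymmetric when one count is zero. How the two lists
should be paired is genuinely underdetermined in the source material;
position-wise pairing of sorted lists is our documented choice, and
surplus entries of the longer list are ignored.

The Friedman statistic is the chi-square form
$\frac{12N}{k(k+1)} \sum_j (\bar R_j - \frac{k+1}{2})^2$ on average
ranks (ties averaged within datasets), and the Nemenyi critical
difference is $q_{0.05}(k)\sqrt{k(k+1)/(6N)}$. Rather than embedding a
quantile table, $q_{0.05}(k)$ is computed exactly as
`qtukey(0.95, k, Inf)/sqrt(2)`, which works for any $k \ge 2$ with no
added dependency.

## Scenarios

* **Fixed k**: cluster at the reference partition's $k$, score by ARI.
* **Best k**: sweep $k \in [2, o]$ and keep the best ARI. The default
  sweep caps the interval at $\min(o - 1, 50)$ because a 50-restart
  k-medoids at every $k$ up to $o$ is disproportionate for large $o$;
  passing `k_range = 2:(n-1)` restores the uncapped interval.
* **Estimated k**: sweep $k$, select by maximum mean Silhouette (ties:
  smallest $k$, a parsimony rule), and only afterwards validate by ARI
  if labels exist — selection is label-blind by construction and tested
  to be.
* **Noise**: replace `round(α% · cells)` distinct cells (round half to
  even) with draws uniform on the original matrix's global range,
  re-cluster at fixed $k$, and report mean ± sd ARI over 100 replicates
  per level, each replicate on a child seed derived from the base seed
  so levels are independently reproducible.

Failed grid cells (e.g. a time-series measure without timestamps) are
recorded as failures, never imputed. Wins/ties/losses between two
clustering methods count every (measure, measure, dataset) comparison,
so a cell over 15 measures and 17 datasets holds
$15 \times 15 \times 17 = 3825$ comparisons.

## Synthetic data: what it emulates, and what not

The sample generator draws cluster mean profiles as
$\mathcal{N}(0, \text{separation}^2)$ per gene and adds
$\mathcal{N}(0, sd^2)$ noise, at dimensions typical of published cancer
compendia (defaults: 60 samples, 500 genes, 3 clusters). The
time-series generator evaluates five fixed shape templates (linear up,
linear down, quadratic peak, quadratic trough, one sinusoid period) at
the timestamps, defaults to ~1000 genes at 10 of the 7-24 timepoints
typical of short stress/cell-cycle courses, and adds a per-gene uniform
offset on $[-2, 2]$: the offset is what separates shape-driven measures
(ranks, slopes) from magnitude-driven ones, and the contrast is tested.
The annotation generator draws gene sets whose members come from one
planted cluster with probability `purity`, so hypergeometric p-values
have closed forms at `purity = 1` and calibrate to no enrichment at the
background rate.

None of this emulates microarray noise structure (dye bias,
intensity-dependent variance), dropout, or correlated genes; passing
the recovery tests shows the pipeline is correct and well-calibrated on
planted Gaussian/shape structure, not that any measure will win on real
data.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: recovery grids use 36-60 objects with 60-100 features, the noise
scenario uses 100 replicates per level on a 36 × 60 fixture, oracle
comparisons use up to $n = 50$ profiles and $n = 30$ objects, and the
Friedman battery uses six 30 × 50 datasets. These sizes were chosen so
every documented property is exercised at full replicate counts while
the whole suite stays fast enough to run habitually.

## Known limitations

* LSS is $O(n^3)$ per pair and intended for short series; building a
  full LSS distance matrix over thousands of genes is expensive.
* GK/KE/WGK are $O(n^2)$ per pair on long (cancer-style) profiles.
* tau-a's tied-self-comparison caveat means a Kendall distance matrix
  can have a positive diagonal; downstream code treats the diagonal as
  given rather than forcing zeros.
* The merge-tie rule is inherited from `hclust`; on data with exactly
  tied dissimilarities, dendrograms may differ from other
  implementations while remaining deterministic here.
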