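---
title: "Higher-order similarity clustering: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order similarity clustering: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hocus)
```

## The problem

Somatic mutation calls, thresholded copy-number profiles and registered
tumor masks are all *sparse*: any two patients share few events, so a
similarity computed directly on the features has poor sensitivity — a pair
with one shared driver mutation and a pair with none look almost the same.
Clustering such similarities under-detects subtypes.

The package takes the social-network view ("a friend of my friend is also my
friend"): two patients may belong together not because they share events,
but because they resemble the *same other patients*. Iterating this idea
produces a ladder of metrics of increasing order, in which transitive
relations are progressively reinforced until community structure emerges.

## The metric ladder

**Order 1 — Hamming similarity.** For samples $j,k$ over $n$ features,

$$ s^{(1)}(j,k) = \frac{1}{n}\sum_{i=1}^{n} I(x_{ij}, x_{ik}), $$

the fraction of features with identical values ($I$ the equality
indicator). It applies unchanged to binary events and to ordinal
copy-number calls in $\{-2,\dots,2\}$, where any identical value counts as
a match. Note that matching *zeros* count: in sparse data the metric is
dominated by shared absence, so its off-diagonal variation is small — this
is precisely the regime where higher orders help.

**Order $d$ — neighborhood correlation.** The order-$d$ matrix treats each
sample's row of the order-$(d-1)$ matrix as its feature vector and
correlates rows:

$$ s^{(d)}(j,k) = \operatorname{cor}\!\big(S^{(d-1)}_{j\cdot},\; S^{(d-1)}_{k\cdot}\big), $$

a centered Pearson correlation with the diagonal entries kept as
coordinates (a sample's strong self-link is part of its neighborhood
profile). Values lie in $[-1, 1]$ and negative entries are retained.

A second, *sum-normalized* variant is available
(`second_order(variant = "sum_norm")`): numerator
$\tfrac1n \sum_l S(j,l)S(l,k)$, denominator
$\sqrt{\sum_l S(j,l)}\,\sqrt{\sum_l S(l,k)}$. This transform is sometimes
written as if it were a row correlation, but it is not one — the
denominator uses plain row sums rather than centered norms and the $1/n$
factor runs against a sum over $m$ samples — and the two variants disagree
numerically. The package defaults to the true row correlation
(`"pearson"`), which is well-defined on signed higher-order input and
matches the "neighborhood similarity" interpretation; the sum-normalized
form is kept for fidelity experiments on non-negative first-order input.
Zero-variance rows (a sample equally similar to everyone) carry no
neighborhood information; their correlations are set to 0 with a warning
rather than propagating `NaN`.

**How many orders?** `order_ladder()` keeps orders $1..K$, stopping early
when the next order's centered kernel alignment with the current one
exceeds `redundancy_threshold` (default 0.999): beyond that point the
transform is a near-monotone rescaling and adds no new relations. The
default `max_order = 4` covers the range in which community structure
emerges in practice; on strongly separable data the ladder typically stops
at 2–3 rungs by redundancy.

**Order vs matrix power.** "Order" counts metric iterations, not matrix
powers. For interoperability with consensus-clustering tools that apply an
internal centered-Pearson metric to their input (which effectively squares
it), `power_features()` implements the convention of supplying
$S^{(d)}$ raised to the $d-1$ power. This package's own
`consensus_cluster()` runs k-means with Euclidean distance directly on the
supplied matrix — there is no internal metric to compensate for — so
`hocus_run()` feeds each rung's similarity matrix in unpowered. The
distinction matters: matrix powering amplifies the leading eigenvector,
which in sparse regimes is a global-density direction rather than a
community contrast, and measurably degrades recovery.

## Consensus clustering and choosing k

`consensus_cluster()` is a Monti-style resampling procedure: for each
candidate $k$, `n_iter` subsamples of the samples (fraction 0.8) and
features (fraction 0.8) are partitioned by k-means (10 restarts, best
inertia kept), and the consensus for a pair is

$$ M_k(i,j) = \frac{\#\{\text{iterations where } i,j \text{ co-clustered}\}}
                  {\#\{\text{iterations where } i,j \text{ co-sampled}\}}. $$

The co-sampled denominator (rather than all iterations) avoids biasing
consensus downward when the sampling fraction is below 1. Pairs never
co-sampled — possible only at very small `n_iter` — are imputed with the
mean observed consensus of their two rows and reported. Final labels at
each $k$ come from average-linkage hierarchical clustering of
$1 - M_k$ cut at $k$.

The number of clusters is chosen from two diagnostics:

* **CDF / delta-area.** The empirical CDF of the upper-triangular
  consensus entries is evaluated on a fixed grid; the area under it grows
  with $k$, and the *relative* increase (delta-area) measures how much
  additional stable structure the extra cluster explains. Candidates up to
  the largest $k$ with relative delta-area $\ge 0.05$ count as stable.
* **Silhouette.** Among stable candidates, the $k$ with the highest
  average silhouette width (computed against $1 - M_k$) wins; ties go to
  the smaller $k$.

The 0.05 stability cut, the average linkage for final labels, and the 0.8
subsampling fractions are declared package defaults — conventional values,
all configurable — not quantities with a single canonical choice.
Reference-scale analyses use `n_iter = 1000` and `k_range = 2:10` (the
package defaults); the bundled tests and the acceptance script scale
`n_iter` down to 100–200, which this procedure tolerates well because
consensus entries are proportions whose Monte-Carlo error shrinks as
$1/\sqrt{n_{\text{iter}}}$.

All randomness flows from one integer seed; a fixed seed plus fixed inputs
reproduces the result object — and the exported TSV/JSON bundle — byte for
byte.

## Outcome-guided order selection

When survival data are available, the order is chosen by how well each
rung's similarity structure agrees with a similarity derived from the
outcome itself.

**Co-survival.** Pairwise absolute differences in survival time
$d_{ij} = |T(i) - T(j)|$ (days) are rescaled to
$s_{ij} = 1 - d_{ij}/\max d$, so values lie in $[0,1]$ with 1 exactly at
tied times. A `variant = "raw"` form, $s_{ij} = (1 - d_{ij})/\max d$, is
retained for comparison; it leaves $[0,1]$ whenever times differ by more
than a day and is not recommended — the default is the transform that
actually fulfills the stated purpose of mapping distances onto $[0,1]$.
By default only patients with a death event enter (censoring times are not
comparable with event times); Kaplan–Meier and log-rank evaluation, by
contrast, use all patients with censoring handled properly.

**Centered kernel alignment.** Two sample-by-sample matrices are compared
by double-centering each (removing row and column means) and taking the
Frobenius inner product normalized by Frobenius norms — a correlation
between kernels, in $[-1,1]$, invariant to additive constants and positive
scaling. `select_order_by_alignment()` returns the *smallest* order within
`parsimony_margin` (default 0.01) of the maximal alignment: when two
orders are statistically indistinguishable, the added complexity of the
higher one is not justified.

**Conditional densities.** `conditional_density()` makes the alignment
inspectable: all sample pairs are split into five (by default)
equal-count bands of feature similarity, and the distribution of outcome
similarity is summarized per band. A distribution that shifts across bands
is the visual counterpart of a positive alignment. Ties in band assignment
are broken by the lexicographic sample-id pair so the partition is stable.

## Evaluation and characterization

* `logrank_evaluate()` excludes clusters with fewer than 5 samples
  (configurable), then runs the standard multi-group log-rank test
  ($\chi^2$, $df = \#\text{groups} - 1$) via the survival package and
  returns tidy Kaplan–Meier curves.
* `gene_cluster_association()` tests each gene against each cluster
  one-vs-rest in a 2×2 $\chi^2$ test of independence without continuity
  correction, reporting the union of per-cluster top-15 gene lists. Raw
  p-values are reported by default (an optional Benjamini–Hochberg
  `q_value` column is available); expected counts below 5 set a
  `low_expected` flag rather than silently switching tests. Top-list ties
  break by p-value, then absolute proportion difference, then gene id.
* `mutation_rate_summary()` reports per-sample event counts, per-cluster
  quartiles and the cohort median; `mutation_rate_groups()` provides a
  generic quantile split by overall burden.

## What the generators emulate — and what they do not

`planted_communities()` draws a block-constant Bernoulli matrix: event
probability `p_in = 0.08` on a sample's own feature block, `p_bg = 0.01`
elsewhere, 120 samples × 600 features in 3 communities by default. This
reproduces the *sparsity* and *weak marginal signal* of mutation data —
expected within-community overlap is ~1 shared event per pair — which is
exactly the regime where order-3 metrics recover communities that order-1
metrics cannot. All-zero rows/columns are redrawn so outputs always pass
the preprocessing invariants; remainders of non-divisible sizes are
assigned round-robin.

`community_survival()` draws exponential event times with per-community
hazards, independent exponential censoring calibrated to a target censored
fraction (rate $\lambda r/(1-r)$ censors a fraction $r$ under an
exponential event model), and a 5-year administrative horizon. Default
hazards are spaced 5-fold (medians ≈ 3, 15, 75 months), matching the
hazard ratio used in the package's two-group power checks.

`voxel_phantom()` builds per-sample sphere masks with jittered centers and
radii on a 32³ grid — a desk-scale stand-in for 1 mm atlas-registered
tumor masks, preserving the two properties the pipeline exercises
(communities defined by location and a volume gradient) and nothing else.

What these generators deliberately omit: gene-length and mutation-signature
effects, hypermutators, correlated events, anatomically realistic tumor
shapes, non-exponential survival and informative censoring. Passing the
bundled tests therefore demonstrates that the machinery is correct and that
higher orders help in the intended sparse regime — not that any particular
clinical cohort will stratify.

## Numerical choices and degenerate inputs

* Similarity matrices are symmetrized (`(S + t(S))/2`) after each
  transform to remove floating-point asymmetry; order-1 diagonals are
  exactly 1.
* The ladder's redundancy rule uses strict `>` so a threshold of 1 always
  builds the full ladder.
* k-means failures on degenerate subsamples (more centers than distinct
  points) are redrawn; more than 10% degenerate iterations abort the run.
* All-identical survival times make the co-survival transform undefined
  and raise an error rather than returning a constant matrix; constant
  matrices likewise make kernel alignment undefined (zero centered norm)
  and error out.
* Unknown MAF variant classes are skipped with a warning by default
  (real files carry extra classes); `unknown = "error"` makes them fatal.
  Matching normalizes case, spaces/hyphens and `_mutation`/`_variant`
  suffixes.
* Voxel features are ordered row-major over $(x,y,z)$ with ids encoding
  grid coordinates, so flattened matrices are reproducible across runs.

## Problem sizes used in the bundled checks

The package's own evaluations (test suite and `scripts/acceptance.R`) use:
the sparse regime at $m=120$, $n=600$, 20 replicate cohorts, consensus at
the true $k$ with `n_iter = 100`; the well-separated regime
($p_{in}=0.9$, $p_{bg}=0.05$, $m=90$, $n=300$) with the full `k_range
= 2:10` and `n_iter = 200`; log-rank calibration with 2000 null replicates
at $n=100$; and power at 200 patients per group with hazards 1.0 vs 0.2.
These sizes give stable rates on a single CPU in a few minutes while
leaving the procedures identical to their full-scale form.

## Known limitations

* Order selection needs an outcome; without survival the pipeline falls
  back to the highest non-redundant order, which favors resolution over
  parsimony.
* Kernel alignment retains the kernel diagonals (the standard definition).
  Both similarity matrices have unit-scale diagonals, so part of any
  alignment score is diagonal-to-diagonal; comparisons are meaningful
  *across orders* (same diagonal structure) rather than as absolute
  effect sizes.
* The χ² association tests are marginal, one gene at a time; they do not
  model mutual exclusivity or burden confounding (the mutation-rate
  summaries exist precisely so burden-driven clusters are visible).
* Consensus clustering inherits k-means' preference for roughly spherical,
  similar-size groups in feature space; heavily imbalanced communities may
  need a wider `k_range`.
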