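# hocus

Higher-order similarity clustering for patient stratification.

Sparse clinical feature data — somatic mutation calls, GISTIC-style
thresholded copy-number profiles, registered tumor voxel masks — share a
problem: any two patients overlap in very few events, so similarities
computed directly on the features are nearly uninformative and clustering
them under-detects disease subtypes. `hocus` takes the network view: two
patients belong together when their *neighborhoods* look alike, even if
their direct overlap is negligible.

The package

1. computes a first-order Hamming similarity between all samples,
   `s⁽¹⁾(j,k) = (1/n) Σᵢ I(x_ij, x_ik)` (the fraction of matching feature
   values; identical copy-number calls count as matches),
2. iterates a neighborhood-correlation transform — order *d* correlates
   rows of the order *d−1* matrix — building a ladder of metrics and
   dropping orders made redundant (kernel alignment with the previous
   order > 0.999),
3. clusters each order with Monti-style resampling consensus clustering
   (k-means on subsampled data; k chosen by consensus-CDF delta-area plus
   average silhouette),
4. picks the metric order whose similarity structure best aligns with a
   co-survival kernel `s_ij = 1 − |T(i)−T(j)|/max d` (centered kernel
   alignment, smallest order within a parsimony margin of the best), and
5. evaluates and characterizes the chosen subtypes: log-rank tests and
   Kaplan–Meier curves (clusters under 5 samples excluded), one-vs-rest
   χ² gene–cluster association tables, mutation-burden summaries, and
   conditional-density band summaries of the feature–outcome relation.

Seeded generators (`planted_communities()`, `community_survival()`,
`voxel_phantom()`) produce sparse planted-community cohorts with coupled
survival and voxel phantoms, so the whole pipeline is testable without
external data.

## Worked example

```r
library(hocus)

cohort <- simulate_cohort(seed = 2)   # 120 samples x 600 features, 3 planted
                                      # communities, sparse (p_in .08, p_bg .01),
                                      # community-driven survival hazards
fit <- hocus_run(cohort$features, cohort$survival,
                 max_order = 3, k_range = 2:5, n_iter = 200, seed = 2)
fit
#> <hocus_fit> 120 samples x 600 features (binary)
#>   orders examined: 1..3; chosen order 3, k = 3
#>   alignment with co-survival: 0.229, 0.309, 0.406

tidy(fit)
#> # A tibble: 3 × 5
#>   order chosen_k silhouette logrank_p alignment
#>   <int>    <int>      <dbl>     <dbl>     <dbl>
#> 1     1        2      0.980  3.13e- 1     0.229
#> 2     2        2      0.882  4.20e- 1     0.309
#> 3     3        3      0.961  1.61e-20     0.406
```

Read the table bottom-up: first-order similarity finds a 2-group split
with no survival separation (log-rank p = 0.31) — in this sparse regime
pairs of samples share roughly one event, so the raw metric carries almost
no community signal. By order 3 the transitive structure has surfaced: the
consensus procedure selects k = 3, the clustering matches the planted
communities (adjusted Rand index 0.78 against truth), the alignment with
the co-survival kernel peaks (0.406), and the clusters separate survival
at log-rank p ≈ 2 × 10⁻²⁰. `glance(fit)` returns the chosen-solution
summary, `fit$association` the per-gene χ² table, and
`autoplot(fit$logrank[[fit$chosen_order]])` the Kaplan–Meier curves.

A thin command-line wrapper with `simulate` / `build` / `run` subcommands
is installed at `exec/hocus` inside the package (for MAF-like mutation
tables, copy-number TSVs, or simulated cohorts).

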