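# scnet — structural covariance networks from regional cortical thickness

Structural covariance (SC) networks describe how the cortical thickness of
brain regions covaries across the subjects of a group: nodes are atlas
parcels (e.g. the 148 Destrieux regions), and edges are the **nonzero
partial correlations** of thickness between regions, selected by an
L1-penalized sparse inverse covariance estimate (graphical lasso). Because
edges are estimated from between-subject covariation, these are group-level
networks, and group comparisons must rebuild whole networks under label
permutation.

`scnet` is for researchers who have per-timepoint subject-by-region
thickness tables (e.g. FreeSurfer exports) plus per-subject behavioural
scores, and who want to test whether behaviourally defined groups differ in
network topology — cross-sectionally and in longitudinal change.

## The model in brief

For each group, columns are standardized and the precision matrix is
estimated from the sample correlation S by maximizing

    log det(Θ) − tr(SΘ) − ρ‖Θ‖₁,off

(block coordinate descent, compiled; diagonal unpenalized). Partial
correlations are r_ij = −θ_ij / √(θ_ii θ_jj); the binary undirected
adjacency keeps |r_ij| > 1e−8. The penalty ρ is cross-validated once on the
whole sample and reused for every group and permutation network.

Three network parameters are computed per network:

- **mean local efficiency** (segregation),
- **global efficiency** (integration),
- **modularity, quantified as the mean participation coefficient** over a
  seeded Louvain partition at resolution 1 — higher participation = less
  segregation.

Group differences (low vs high median-split groups, per behavioural
component) are tested by re-estimating both networks under random
reallocation of subjects (5,000 shuffles in the reference design), with
add-one two-tailed p-values and Benjamini–Hochberg FDR across components.
A difference-in-differences permutation test handles the Time2 − Time1
change contrast. A synthetic longitudinal cohort generator with planted
block covariance makes the whole chain testable without subject data.

## Worked example

Simulate a cohort at the reference design's scale with a planted
segregation effect (the low-warmth group's between-module correlation
scaled by 0.4), then test the group difference in modularity:

```r
library(scnet)

cfg    <- synthetic_config(n_subjects = 114, n_regions = 60, n_modules = 4,
                           group_effect = 0.4, seed = 7)
cohort <- generate_cohort(cfg)
groups <- median_split(cohort$component_scores, "warmth")
z2     <- standardize_regions(cohort$thickness_t2)

cv  <- select_regularization(z2, k_folds = 5, seed = 7)
net <- estimate_sparse_network(z2, cv$rho)
net
#> Sparse structural covariance network: 60 regions, 484 edges (density 0.273)
#>   rho = 0.10467, estimated from 114 subjects

compute_network_metrics(net, resolution = 1, seed = 7)
#> Network metrics
#>   mean local efficiency:  0.6912
#>   global efficiency:      0.6289
#>   mean participation:     0.4860 (4 modules, Q = 0.4029)

permutation_test(z2, groups, "participation", rho = cv$rho,
                 n_perm = 500, seed = 7)
#> Permutation test: warmth, participation (T2)
#>   low = 0.5411, high = 0.7133, diff (low - high) = -0.1722
#>   p = 0.0020 (500 permutations, rho = 0.10467)
```

Reading the output: the whole-sample cross-validated penalty is ρ ≈ 0.105;
at that penalty the low-warmth group's network has a mean participation
coefficient of 0.54 against 0.71 for the high-warmth group — its edges
concentrate within modules, i.e. it is more segregated — and only 1 of 500
label shuffles produced as extreme a difference (p = 0.002), recovering
the planted effect with the expected direction.

The end-to-end pipeline (QC → penalty selection → median splits →
covariate screen → all components × metrics × contrasts → FDR → CSV/JSON
artifacts) is one call:

```r
res <- run_pipeline(run_config(synthetic = cfg, n_perm = 1000,
                               master_seed = 1, output_dir = "out"))
res$tables$participation   # reference-style results table per metric
```

A thin command-line front end with `simulate`, `qc`, `build-networks`,
`metrics`, `compare` and `run-all` subcommands lives at
`inst/cli/scnet.R`.

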