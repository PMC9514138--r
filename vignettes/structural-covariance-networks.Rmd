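---
title: "Structural covariance networks from cortical thickness: model, estimation and inference"
author: "scnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

A structural covariance (SC) network is a group-level description of how
regional brain morphometry covaries across people. Its nodes are cortical
regions (here, parcels of a whole-cortex atlas such as the 148-region
Destrieux parcellation) and its edges record a statistical dependence
between the cortical thickness of two regions, measured across the subjects
of a group. Because the edges are estimated from between-subject
covariation, an SC network characterizes a *group*, not an individual. Any
comparison between groups therefore has to re-estimate whole networks, and
inference has to respect that: significance is assessed by permuting group
labels and rebuilding networks, not by subject-level statistics.

`scnet` implements this whole chain for longitudinal designs with two
assessments: reading and screening thickness tables, forming behavioural
groups by median split, estimating one sparse partial-correlation network
per group, computing segregation/integration graph metrics, and testing
group differences (cross-sectional and change) by label-permutation with
false-discovery-rate control. A synthetic cohort generator with a planted
covariance structure makes every stage testable without access to any
subject data.

## Network definition and estimation

Edges are defined by *partial* correlations: the dependence between two
regions after removing variance shared with all other regions. Working with
partial rather than marginal correlations absorbs global covariates (total
thickness, age trends, scanner effects) to the extent that they act through
the other regions, which is why the pipeline deliberately has no
covariate-residualization step.

Given the subjects-by-regions matrix for one group, columns are
standardized and the sample correlation matrix \(S\) is formed. The
precision matrix \(\Theta\) (inverse covariance) is estimated by the
graphical lasso, maximizing the L1-penalized Gaussian log-likelihood

\[
\log\det\Theta \;-\; \operatorname{tr}(S\,\Theta)\;-\;\rho\,
\lVert\Theta\rVert_{1,\mathrm{off}},
\]

where the penalty applies to off-diagonal entries only. The solver is a
block coordinate-descent over columns of the working covariance (each
column update is itself a lasso solved by coordinate descent), implemented
in compiled code because permutation inference refits on the order of
\(10^5\) networks. The fitted partial correlations are
\(r_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}\), and the binary
undirected adjacency keeps the nonzero ones
(\(|r_{ij}| > 10^{-8}\), a numerical floor absorbing solver noise). Tests
verify the solver against the Karush–Kuhn–Tucker stationarity conditions of
the objective — \(|(\Theta^{-1})_{ij} - S_{ij}| \le \rho\) off-diagonally,
with equality \(\rho\,\mathrm{sign}(\theta_{ij})\) on selected edges and
\((\Theta^{-1})_{ii} = S_{ii}\) — and against an independently computed
reference solution.

Two conventions matter and are fixed throughout:

* **Correlation scale.** Estimation is always on standardized data, so
  \(\rho\) is comparable across datasets and groups. A reported
  whole-sample value (such as the 0.184 of the reference study design) is
  only meaningful on this scale.
* **One penalty for every comparison.** The penalty is chosen once on the
  whole sample and reused for every group and permutation network, so
  group differences cannot arise from differential regularization. In
  `run_pipeline()` the penalty is cross-validated on the baseline
  assessment (all subjects, one row per subject); stacking both timepoints
  would double the row count and systematically halve the selected
  penalty, changing the sparsity regime that a single whole-group value
  describes.

### Choosing the penalty

`select_regularization()` performs k-fold cross-validation (default k = 5)
over a log-spaced grid (default 30 values from 0.01 up to the empirical
ceiling \(\max_{i\ne j}|S_{ij}|\), above which the network is empty). Each
fold's fit is scored by the Gaussian log-likelihood of the held-out
subjects, centered and scaled with training-fold statistics. The default
selection is the argmax of the mean held-out log-likelihood, with ties
broken toward the sparser (larger) penalty.

Likelihood cross-validation is tuned for predictive risk, and it is a
well-known property of the graphical lasso that this choice *over-selects*:
at the argmax penalty, essentially all true edges are recovered but a
substantial number of spurious ones come along. When the goal is support
(edge-set) recovery rather than prediction, the standard remedy is the
one-standard-error rule — take the largest penalty whose mean held-out
log-likelihood is within one SE (across folds) of the maximum —
available as `rule = "1se"`. On data simulated from a sparse planted
precision (20 regions, 1,000 subjects, edge density 0.1, partial
correlations about 0.2), the 1-SE choice with 10 folds recovers the edge
set with a median F1 of 1.0 over ten simulations, whereas the argmax choice
yields F1 near 0.5–0.6 driven entirely by false positives. Group-comparison
pipelines use the default argmax rule; the 1-SE rule is the documented
choice for structure-recovery analyses.

## Graph metrics

All metrics operate on the binary undirected adjacency.

* **Global efficiency** — the mean over node pairs of the inverse
  shortest-path length, with disconnected pairs contributing 0. An
  integration measure in \([0, 1]\).
* **Mean local efficiency** — per node, the global efficiency of the
  subgraph induced by its neighbours (the node excluded); nodes with fewer
  than two neighbours score 0; averaged over all nodes. A segregation
  measure.
* **Modularity, quantified as the mean participation coefficient.** A
  Louvain partition at resolution \(\gamma\) (default 1) is computed for
  the network, then each node's participation coefficient
  \(\mathrm{PC}_i = 1 - \sum_s (k_{is}/k_i)^2\) measures how its edges
  spread across modules; the network value is the mean over all nodes
  (isolated nodes score 0). **Interpretation contract:** a *higher* mean
  participation coefficient means edges are spread across modules, i.e.
  *less* segregation; lower values mean more segregated networks. The
  Newman–Girvan quality Q of the partition is attached as a diagnostic
  only.

The efficiency implementations are verified exactly (to 1e-12) against a
brute-force oracle using boolean matrix-power distances, and the community
step against exhaustive partition search, on hundreds of random graphs of
up to 8 nodes.

Averaging the participation coefficient over *all* nodes (not only
non-isolated ones) is a deliberate convention, stated here because the
alternative changes values on sparse networks.

## Group formation and the covariate screen

Behavioural component scores (four components in the reference design) are
dichotomized at the sample median: below-median subjects form the low
group, above-median the high group. Scores exactly at the median are
assigned deterministically in stable subject-ID order, alternating toward
the smaller group, so sizes differ by at most one and repeated runs agree
exactly; with 114 distinct scores this yields the 57/57 design. The split
depends only on ranks, hence is invariant to monotone rescaling of the
scores.

Before network comparison, each candidate confounder (age, sex, symptom
scores, occupational status, ...) is screened for low/high group
differences: one-way ANOVA for numeric covariates (with two groups,
F = t²), chi-squared for binary ones, all pooled into a single
Benjamini–Hochberg family (24 tests in the reference design: 4 components
by 6 covariates). The screen is a *gate and report*: when it is null the
pipeline proceeds without adjustment, mirroring the partial-correlation
rationale above; it never silently regresses covariates out.

## Permutation inference

For a component and metric, the observed statistic is the low-group metric
minus the high-group metric, each computed from that group's own network at
the shared penalty. Under the null of no group difference, subjects are
exchangeable, so the null distribution is built by randomly reallocating
subjects to two groups of the original sizes (the median split fixes
57/57-style sizes) and recomputing both networks and the statistic — 5,000
times in the reference design. The two-tailed p-value uses the add-one
count

\[
p = \frac{1 + \#\{|T^\ast| \ge |T_{\mathrm{obs}}|\}}{1 + n_{\mathrm{perm}}},
\]

which implements the same decision rule at \(\alpha = 0.05\) as
thresholding at the 95th percentile of \(|T^\ast|\) but returns a usable
p-value (never exactly zero) for FDR adjustment.

The **omnibus change contrast** asks whether the Time-2 minus Time-1 change
in a metric differs between groups. The statistic is the difference in
differences,
\((m^{low}_{T2} - m^{low}_{T1}) - (m^{high}_{T2} - m^{high}_{T1})\), and
each permutation reallocates *subjects* — carrying both their timepoints
together — before rebuilding the four networks. This is one defensible
construction of a change contrast for group-level networks; it is stated
here explicitly because omnibus tests on SC networks are often reported
without a definition.

FDR families follow the reporting layout: the four components within one
metric-by-contrast table form one Benjamini–Hochberg family (the 24-way
family is reserved for the covariate screen). Time-1 cross-sectional values
are reported descriptively without permutation tests by default (a
`test_t1` flag enables them), matching the reference design's reporting
convention.

Every random step derives a child seed from the master seed per
(component, metric, contrast), so a single table cell can be reproduced in
isolation and a full run is byte-identical given the master seed.
Permutations run serially; there is no parallel mode, so results cannot
depend on worker count.

## The synthetic cohort generator

`generate_cohort()` draws a two-timepoint cohort from a planted model:

* **Thickness.** Regions carry a block-structured population correlation:
  `within_module_corr` inside each of `n_modules` contiguous blocks,
  `between_module_corr` across blocks, normal marginals with mean 2.5 mm
  and SD 0.1 mm. Normal marginals are the standard working assumption for
  covariance analysis; the defaults (114 subjects, 148 regions, 4 modules)
  mirror the reference design's dimensions.
* **Longitudinal dependence.** Time 2 is an equicorrelated redraw:
  \(X_2 = c\,X_1 + \sqrt{1 - c^2}\,E\) per region with test–retest
  correlation \(c\) = `timepoint_corr` (default 0.7) and innovations drawn
  from the same planted correlation. This is the simplest structure that
  supports a change analysis; it is not an autoregressive growth model.
* **Component scores.** Four uncorrelated scores from standardized
  sign-flipped log-normals with target skewness per component (defaults
  1.98, 0.23, 0.89, −1.80, the reference study's printed values).
* **Planted group effect.** Subjects below the median of the warmth-like
  component form the low group; `group_effect` scales that group's
  between-module correlation (1 = null). A
  `group_effect_timepoint = "T2"` option restricts the effect to the
  second assessment for studying change contrasts.

### Why the default correlations are 0.55 / 0.52

Cortical-thickness covariance is dominated by a strong global factor, with
modular differentiation that is real but subtle; the defaults
(`within_module_corr = 0.55`, `between_module_corr = 0.52`) encode exactly
that regime. They are also the regime in which a planted segregation
effect expresses itself in partial-correlation networks, for a reason
worth recording. In a block-equicorrelated model the *partial* correlation
between regions of different modules is of order \(b/k^2\) for block size
\(k\) — a few thousandths at 60 regions — for *every* admissible
\((w, b)\): uniform between-module dependence is explained away by
conditioning on the other regions. A group difference planted directly on
\(b\) is therefore invisible edge-by-edge. What does carry through is the
global/modular balance: as \(b\) approaches \(w\), the whole matrix
approaches one equicorrelated block and the *within*-module partial
correlations collapse toward the \(1/p\) scale, whereas a group whose
\(b\) is scaled down (say by 0.4) retains within-module partials on the
much larger \(1/k\) scale. The scaled (low) group then yields a sparse
network concentrated inside modules — lower participation coefficient,
more segregation — while the unscaled group's network is more diffuse.
With the defaults, a planted `group_effect = 0.4` at 114 subjects and 60
regions is detected by the mean-participation permutation test in roughly
three-quarters of simulated cohorts, always in the planted direction
(lower warmth group more segregated), which is the regime the acceptance
analyses exercise.

What the generator does *not* emulate: empirical CT covariance spectra,
spatial autocorrelation on the cortical sheet, hemispheric symmetry,
site/scanner effects, non-normal thickness marginals, or item-level
questionnaire structure. Passing tests on synthetic cohorts therefore
demonstrate the *statistical machinery* — calibration, directionality,
reproducibility — not fidelity to any particular cohort's covariance.

## Numerical choices and degenerate inputs

* Nonzero edge: \(|r_{ij}| > 10^{-8}\); solver convergence: mean absolute
  off-diagonal change below `tol` (1e-4) times the mean off-diagonal
  magnitude of \(S\), at most 200 sweeps; non-convergence is an error (and
  inside permutation loops, a redraw with a budget of twice `n_perm`).
* \(\rho = 0\) demands an invertible sample correlation (more subjects
  than regions), otherwise the fit is refused with a message asking for a
  positive penalty.
* z-scores (QC and standardization) use the sample SD (n−1); QC flags are
  reported, never auto-removed (default threshold 3.0).
* Zero-variance regions are a hard error at standardization; constant
  regions produce no QC flags.
* Edgeless graphs: all metrics 0, all-singleton partition; isolated nodes:
  efficiency and participation 0, singleton modules.
* Louvain is seed-controlled; identical adjacency and seed give identical
  partitions and metrics.

## Problem sizes used by the shipped analyses

The reference design's full scale (148 regions, 5,000 permutations per
contrast) is the default for real use. The shipped test-suite analyses
use scaled-down sizes chosen as the package's own verification conditions:
calibration on 200 null cohorts of 40 regions with 500 permutations at
\(\alpha = 0.05\); planted-effect recovery on 50 cohorts of 60 regions
with 200 permutations; structure recovery at 20 regions and 1,000
subjects. Calibration is checked on global efficiency — under the null the
permutation test's exactness follows from exchangeability alone and is
metric-agnostic, and global efficiency avoids a Louvain call in each of
the 100,000 refits — while the planted-effect analysis uses the mean
participation coefficient, where the effect is planted.

## Known limitations

* Group-level networks mean no subject-level inference; effects are
  attributed to groups, not individuals.
* The graphical-lasso edge set at a likelihood-CV penalty over-selects;
  edge lists at the default penalty should be read as a superset of the
  plausible structure (use `rule = "1se"` for support recovery).
* The omnibus change test is one construction among several possible; its
  definition is explicit above and in the function documentation.
* Louvain is a greedy heuristic; on small or degenerate graphs the
  partition may not be the global modularity optimum (tests bound it
  against exhaustive search on tiny graphs only).
* The synthetic model's simplifications listed above.
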