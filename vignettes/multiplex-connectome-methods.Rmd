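---
title: "Methods: multiplex gray-matter and amyloid connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex gray-matter and amyloid connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxad)
```

## The model

`mxad` treats each diagnostic group as a two-layer multiplex network over a
fixed 72-region atlas. The layers are *structural covariance* networks: an
edge between two regions is the Pearson correlation, across the subjects
of that group, of the regions' measurements after removing age and sex by
per-region ordinary least squares. Residualizing first and correlating
pairwise is algebraically the partial correlation given the covariates,
and it remains well-posed at the study's smallest group size (67), where a
72-node inverse-covariance estimate would not be. Because covariance
networks are group-level objects (one network per group, not per subject),
all between-group inference is permutation-based.

Subject-level preprocessing follows the clinical conventions of
amyloid-stratified designs: CSF amyloid-beta 42 values above the assay's
validated ceiling are replaced by 1700 pg/ml; amyloid positivity is CSF
amyloid-beta 42 strictly below 976.6 pg/ml; subcortical volumes are
head-size-corrected by
`Adjusted = Observed − β (TIV − mean TIV)`, with the slope β estimated per
region and the centering mean taken over all analyzed subjects.

Two conventions are deliberately exposed as configuration because the
field is not uniform about them:

- **Negative partial correlations.** Weighted analyses (overlapping
  strength, community detection) use positive weights only by default,
  consistent with keeping the strongest positive correlations at
  binarization and with non-negative strength sums; `absolute` and `raw`
  modes are available.
- **β's reference subjects for TIV adjustment.** Default: the
  amyloid-negative control group, the common choice for estimating a
  nuisance slope free of disease effects; any subset (or all subjects) can
  be used. Residualization on age/sex is done within each diagnostic group,
  since networks are per-group. Residuals are affinely invariant to the 0/1
  sex coding (asserted by test).

## Binarization and the density grid

Binary analyses threshold each layer to exactly `round(D·N(N−1)/2)` edges
for densities 2–30 % in 1 % steps (29 grids), ranking signed weights
descending with deterministic lexicographic tie-breaks. The lower bound
keeps the edge count above the node count; the upper bound is where the
small-world index (clustering/path-length ratio versus 20 Maslov–Sneppen
degree-preserving rewires) stays above 1. Matching edge counts across
layers, groups, and densities removes the density confound from every
binary measure; the edge sets are nested along the grid by construction.

## Community detection

The two-layer modularity uses closed-form Newman–Girvan null models
`s_i s_j / (2m)` per layer — the analytic expectation of
strength-preserving edge rewiring, chosen over explicit rewiring for
determinism — and an identity inter-layer coupling of weight ω that
rewards keeping a node's two replicas in one community. Optimization is a
generalized Louvain: greedy local moves plus aggregation on the 2N × 2N
supra-modularity matrix, iterated to a fixed point, best of `n_restarts`
(default 100) seeded restarts by Q, ties to the first found. Labels live
in one space across layers, so per-layer assignments are directly
comparable and persistence (the fraction of nodes with one label in both
layers) is well defined.

Q is normalized by the total weight including the `2ωN` coupling mass. Any
positive rescaling of this normalization leaves the optimizing partition
unchanged (tested); Q values are therefore comparable only within this
convention, which is recorded in output metadata.

For model selection over the γ × ω grid ({0.5, 0.8, 0.9, 1, 1.1, 1.2, 2} ×
{0.25, 0.5, 0.75, 1}), the package computes all pairwise normalized
variation-of-information distances and selects the grid point with minimal
mean VI to all others — an explicit stability criterion, since picking the
most stable parameter pair with a sensible module count is otherwise a
judgment call; the selection is a default, not a constraint, and defaults
γ = 1, ω = 1 can be set directly.

## Permutation inference

Group contrasts permute *subjects* (covariates travel with the subject),
rebuilding both groups' full pipelines — residualization, correlation,
binarization at every density — in each of the (default) 10 000
replicates; anything less than a full rebuild changes the null. P-values
are two-tailed with the add-one convention `(#{|null| ≥ |obs|} + 1)/(B +
1)`, bounded away from 0. Binary measures are tested at each of the 29
densities and the per-region p-values averaged; the weighted strength has
no density loop. FDR control is Benjamini–Hochberg at q = 0.05 across the
72 regions, per (measure, contrast) family; contrasts are not pooled.

A caveat that matters for real data: the permutation null assumes the two
groups share one generative process. Groups that differ strongly in mean
level (e.g., amyloid SUVR across the AD continuum) are not exchangeable in
mean, and mixture effects can make covariance-based tests mildly
anticonservative; calibration checks here therefore split one generated
group in half, the sharpest form of the null.

## The synthetic cohort generator

The generator emulates the *statistical structure* the pipeline assumes,
not any real atrophy topography: four groups (default sizes 135/67/179/132
matching the study composition), 72 regions, and per-group multivariate
normal regional values with a planted block correlation matrix (default 3
equal modules, within-module correlation 0.5, between 0.1 — typical of
structural covariance blocks). Confounds are added deliberately so the
pipeline has something to remove: a common age slope (−0.02 latent units
per year) and sex offset (0.3), i.i.d. measurement noise (sd 0.2,
attenuating all correlations by `1/(1 + 0.04)`), multiplicative TIV
scaling of subcortical volumes, and group-graded amyloid SUVR means (1.05
to 1.45). CSF amyloid-beta 42 is drawn from truncated normals on the
correct side of 976.6 pg/ml per group (negatives may exceed the 1700
ceiling, exercising the clamp), so stratification reproduces the
configured group sizes exactly. Disease effect on connectivity is a
uniform, stage-weighted (0, 1/3, 2/3, 1) increment of *all* amyloid-layer
correlations (default 0.25 at full stage): amyloid burden raises
covariance across the layer, which shifts every node's strength without
changing the modular contrast. An optional `layer_disagreement` fraction
reassigns regions to different amyloid-layer modules to dial expected
persistence below 1; the default is 0 (shared partition).

What passing tests on these cohorts do *not* show: robustness to
non-Gaussian marginals, spatially autocorrelated noise, site effects, or
topographically realistic covariance — the generator makes no attempt at
those, and results on real data depend on them.

## Numerical choices

- Planted correlation matrices are repaired by eigenvalue clipping and
  unit-diagonal rescaling only if indefinite (the defaults never need it).
- Binarization tie-breaks: weight descending, then lexicographic (i, j);
  if positive weights run out, negative weights are admitted by rank with
  a recorded warning.
- Louvain move gains use a 1e−12 improvement threshold; non-convergence
  after 1000 passes is an error, never a silent truncation.
- Degenerate inputs fail loudly and by name: constant regions after
  residualization, rank-deficient covariate designs, zero TIV variance in
  the β-source, zero-weight layers, missing density columns.
- All randomness (generator, Louvain restarts, permutations, rewiring) is
  seed-controlled; repeated runs of one configuration are byte-identical.

## Problem sizes used in the shipped checks

The test suite exercises the study-shaped configuration (72 regions,
groups up to 179 subjects) for network construction and community
recovery; permutation calibration uses 20 replicate cohorts of 100 + 100
subjects at 1000 permutations, and power checks use the default effect
with 135 vs 132 subjects at 1000 permutations across 10 cohort seeds.
These sizes give stable Monte-Carlo estimates (binomial s.e. ≈ 0.006 on a
0.05 rejection rate) while keeping a full run of the suite in the
single-digit minutes.

## Known limitations

- Exactly two layers; the quality function is written for the two-layer
  case and the types would need widening for M > 2.
- Group-level networks only — no subject-level (jackknife) variants.
- No spatial-autocorrelation-preserving null models; the permutation null
  addresses group exchangeability, not spatial structure.
- Q values are convention-dependent (see above) and should not be compared
  across implementations without checking the normalization.
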