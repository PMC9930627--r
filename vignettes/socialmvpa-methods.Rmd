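---
title: "Methods: synthetic cohorts, decoding schemes, and representational analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, decoding schemes, and representational analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

socialmvpa implements a complete multivoxel pattern analysis (MVPA)
pipeline for a social-cognition factorial design: four person identities
(`PresentSelf`, `PastSelf`, `Mother`, `Queen`) crossed with two sides of
emotive valence, measured as one GLM beta vector per condition per
scanning run in each region of interest (ROI). This vignette documents
the generative model behind the synthetic cohort, the decoding and
representational machinery, the numerical decisions taken where the
design was genuinely open, and what the synthetic benchmarks do and do
not establish about real data.

## The generative model

Real fMRI beta patterns for this design are not distributable, so the
package ships a generator whose output has the statistical structure the
analyses assume. Generation starts at the level of beta estimates: no
BOLD time series, hemodynamic convolution, or GLM fitting is simulated.

Each condition is a point in a low-dimensional latent space
(`latent_dim = 6` by default; only the first three axes are used):

* **Axis 1 — self/other.** The aggregate self (`PresentSelf`,
  `PastSelf`) and aggregate other (`Mother`, `Queen`) centroids sit
  `d_self_other` apart. Default 2 (in units of the voxel noise SD).
* **Axis 2 — social distance (near/far).** The socially near members of
  each domain (`PresentSelf`, `Mother`) and the far members (`PastSelf`,
  `Queen`) sit `d_distance` apart. Default 1. Because this axis is
  *shared* across the two domains, distance information learned on the
  self pair generalizes to the other pair, which is exactly what the
  cross-classification schemes probe. Keeping `d_distance <
  d_self_other` nests the distance gradient inside the principal
  self/other split.
* **Axis 3 — valence.** `d_valence` separates the positive and negative
  variant of each person. Default 0: identity coding is
  valence-invariant, so the cross-valence analyses have planted signal
  and the valence factor of the network ANOVA has none.

Setting all three separations to zero defines the null, signal-free
geometry used for chance calibration.

Per ROI, the latent means are pushed into voxel space through a random
loading matrix with orthonormal, zero-mean columns, scaled by the ROI's
`info_scale`. Orthonormality makes the planted discriminability equal to
`info_scale` times the latent separation, independent of voxel count;
the zero-mean constraint makes every embedded signal average to zero
across voxels, so conditions differ in *pattern* but not in mean
amplitude — the univariate/multivariate dissociation is true by
construction, and `univariate_contrast()` should find nothing reliable
while decoding succeeds.

Noise is additive Gaussian at two levels, the minimal model consistent
with how GLM beta estimates behave: a run-level offset vector shared by
the eight conditions of a run (`noise_sd_run`, default 0.5) and
independent voxel-level noise per condition-by-run estimate
(`noise_sd_voxel`, default 1). Subjects share the latent geometry up to
a Gaussian jitter of the condition means (SD = 10% of `d_self_other`),
applied once per subject and shared by all of that subject's ROIs; this
keeps group structure recoverable while making noise-ceiling brackets
nondegenerate.

The default cohort mirrors the study design it emulates: 24 subjects, 8
runs, 8 conditions (hence 64 beta vectors per ROI), and 8 ROIs — five
default-network regions (dmPFC, vmPFC, PCC, left/right IPL) with
`info_scale = 2` and three semantic-network regions (left/right ATL,
left IFG) with `info_scale = 1`. The 2:1 ratio was chosen once so that
group accuracies fall in the regime reported for this kind of design
(binary self/other decoding near 85–90% in DN and 65–70% in SN; 4-way
decoding well above the 25% chance level) while SN regions remain above
chance. All ROIs share one voxel count (default 80, about the size of a
10-mm sphere at 3-mm voxels) so that combinatorial joint patterns are
exactly dimension-matched without subsampling.

Behavioral similarity ratings (0 = most dissimilar, 100 = most similar)
are drawn per subject around configurable pair means and clipped to the
scale. The defaults encode the qualitative pattern reported for this
task — the mother rated closer to the present self than the past self
is, the Queen distant from everyone — and are deliberately
configurable, because per-subject rating distributions are not published
for this design.

```{r}
library(socialmvpa)
spec <- cohort_spec() # 24 subjects, 8 runs, 8 ROIs
cohort <- simulate_cohort(spec)
ratings <- simulate_behavioral_ratings(spec, seed = 2)
```

## Decoding

All decoding uses a linear support vector machine with cost fixed at
C = 1 (libsvm via e1071), no hyperparameter search, and no feature
scaling by default. Whether the original toolboxes scaled features is
not documented for this design; scaling is therefore exposed as
`classifier_settings(scaling = "train_fold_zscore")` (statistics
estimated on the training fold only) rather than guessed as a default.
Multiclass problems use one-vs-one voting, the conventional linear-SVM
default.

Seven schemes are declared in `make_scheme()`: three binary
cross-validation schemes (self vs other, present vs past self, mother
vs queen), the 4-way person scheme, and three cross-classification
schemes (self/other across social distance, near/far across the
self/other domain, 4-way across valence). Cross-validation is
leave-one-run-out: one fold per run, so train and test sets never share
a run. Cross-classification trains on one condition partition and tests
on the disjoint partition, in both directions, averaging the two
accuracies; all runs contribute to both sides because generalization is
across conditions, not runs. Accuracy is example-weighted within fold
and fold-averaged overall.

```{r}
accuracy <- decode_cohort(cohort)
plot_accuracy(accuracy)
```

## Combinatorial-ROI decoding

`combinatorial_matrix()` concatenates every ordered ROI pair voxel-wise
and subtracts the row ROI's single-ROI baseline:
`delta[r, c] = accuracy(r + c) − baseline(r)`. Rows are the "original"
ROI, columns the "added" ROI. A region's mean column is its
*contribution* (what it gives to others); its mean row is its *benefit*
(what it gains). The matrix is asymmetric by design, and both the raw
ordered deltas and their summaries are emitted, since averaging the two
orientations of a pair is a display choice, not a statistic. Unequal
voxel counts are refused unless explicit seeded subsampling is
requested, because matched feature counts are what make the deltas
comparable.

## Searchlight and ROI definition

`run_searchlight()` decodes the in-mask sphere neighborhood
(center-to-center distance ≤ radius in millimeters; default 10 mm)
around every in-mask voxel with the identical leave-one-run-out engine,
so the map value at a centroid equals the ROI decoder run on that
sphere. Group inference is a voxel-wise one-sample t test against
chance with familywise error controlled by max-statistic sign-flip
permutation: exact under exchangeability, distribution-free, and
feasible at desk scale, in place of random-field-theory correction
(which, together with spatial normalization and smoothing of accuracy
maps, is out of scope for synthetic pre-aligned grids). Voxels with
zero between-subject variance have no defined t; they are flagged and
excluded from the max statistic. Corrected p values use the (1 + count)
/ (permutations + 1) convention.

`define_roi_from_tmap()` reproduces the localizer-style threshold
ladder: threshold the t map at p < 0.001, then 0.005, then 0.01, stop
at the first level with suprathreshold voxels, take the suprathreshold
local maximum nearest the landmark (Euclidean millimeters; local maxima
are strictly greater than all 26-connected in-mask neighbors, plateau
ties resolved toward the smallest linear index), and return the 10-mm
sphere centered there. When no level survives, the result says so
explicitly rather than returning a silently empty mask.

Voxel grids are indexed 1-based throughout, the R convention; physical
coordinates are `index × voxel_size_mm` with an identity affine.

## Representational similarity

Condition patterns for RSA are run-averaged betas per condition (run
handling is not documented for the original analyses; per-run
alternatives would mainly add noise at these sample sizes, and the
run-averaged form is the common default). Similarity is the Pearson
correlation of vectorized patterns; dissimilarity is 1 − r, and every
second-order statistic uses only the lower triangle (28 entries at the
eight-condition level, 6 at the four-person level).

Second-order comparisons use Kendall's tau-a — (concordant −
discordant) / (n(n−1)/2), with *no* tie correction, implemented in the
package because base R's Kendall coefficient is the tie-corrected
tau-b — and Spearman's rho on midranks. Tau-a is the appropriate index
against categorical model matrices with tied entries, but note its
ceiling: the tau-a of a tied vector with itself is below 1, which is
why exact-recovery examples in the tests use rho.

Group inference on coefficients uses the signed-rank test (one-tailed
against zero; two-tailed for pairwise model contrasts), exact by full
enumeration of sign assignments for n ≤ 12 retained differences and a
continuity- and tie-corrected normal approximation above; zero
differences are dropped (Wilcoxon's convention — the original analyses
do not state one). Bonferroni correction runs over the 8 ROIs
(0.05 / 8 = 0.006 at the precision usually printed).

Model RDMs over the four persons: *binary* (0 within the self pair and
within the other pair, 1 between), *graded* (|position difference| on
the equidistant 0–3 spectrum), and *behavioral* ((100 − rating)/100, a
linear transform — the only scale information available). Model
comparison correlates each subject/ROI neural dissimilarity with each
model, tests per ROI, contrasts models on per-subject coefficients
averaged over ROIs, and attaches the leave-one-subject-out noise
ceiling averaged across regions (upper bound: correlation with the
group mean including the subject; lower: excluding).

Hierarchical clustering of 1 − r (or 1 − tau/rho) matrices uses average
linkage (UPGMA). The linkage used by the original analyses is unstated;
average linkage is the common choice for correlation-derived distances
and is recorded here as a decision, not a claim. Merges are
deterministic, verified against a brute-force agglomeration oracle;
trees export to Newick via ape.

The within/between-network ANOVA is computed per subject and valence
context from all region pairs (within-network pairs versus
between-network pairs averaged separately), then analyzed as a 2
(membership) × 2 (valence) within-subject design with partial eta
squared per effect. Whether the original analysis aggregated over all
28 pairs or over network means is unstated; the pair-level aggregation
is used here and the per-pair coefficient table is returned alongside
so either aggregation can be recomputed.

```{r}
mc <- model_comparison(cohort,
  models = c("binary", "graded", "behavioral"),
  ratings = ratings
)
mc$by_roi
```

## Degenerate inputs and numerical conventions

Batch runs over many ROIs and simulations must not die on degenerate
cells, so zero-variance situations yield *flagged* results rather than
errors: a zero-variance accuracy vector gives a degenerate t (p 0 or 1
by the sign of the mean), all-zero signed-rank differences give p = 1,
constant inputs to rank correlations return `NA` with a warning, and
zero-variance patterns are reported when a similarity matrix is built.
Errors are reserved for structural mistakes: mismatched condition/run
structure, overlapping cross-classification partitions, missing design
cells, spheres outside the grid.

All randomness is seed-controlled. A cohort is bit-identical for an
identical spec and seed; `run_full_analysis()` writes byte-identical
tables for an identical config and seed, with per-stage sub-seeds
derived from the master seed.

## Problem sizes

The shipped benchmarks are sized for a single desktop core: chance
calibration uses 200 signal-free 80-voxel ROI datasets per scheme;
planted-structure recovery uses the full default cohort (24 subjects ×
8 ROIs × 64 patterns); familywise-error calibration uses 100 null
cohorts of 12 simulated accuracy maps on a 12³ grid with 499 sign-flip
permutations each; searchlight recovery uses a 9³ grid with a planted
5-mm sphere. These sizes were chosen so each property is measured with
comfortable Monte-Carlo margins.

## What the synthetic benchmarks do and do not show

Passing tests establish that the pipeline recovers planted structure:
chance-level behavior on signal-free data, perfect decoding on
noise-free separable data, correct orientation of the DN/SN asymmetry,
confusion gradients that follow planted distances, dendrograms that
split on the planted principal axis, and model comparisons that prefer
the generating model. They do not establish anything about real brains:
the generator's noise is Gaussian and exchangeable across voxels, runs
are homogeneous, subjects are aligned by construction, and the latent
geometry is exactly low-dimensional — all idealizations that real beta
series violate. Estimates of *method* behavior (fold hygiene, FWE
control, statistic correctness) transfer; estimates of *effect sizes*
do not.

Other known limitations: no trial- or block-level beta estimation, no
spatial normalization or smoothing, no triple-wise ROI combinations, no
whole-brain RSA searchlight, and ROI-level analyses assume every ROI of
a subject shares the run structure.
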