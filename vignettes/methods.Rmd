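---
title: "Methods: from tumor MRI texture to CD3 infiltration status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tumor MRI texture to CD3 infiltration status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd3radiomics)
```

## The problem

Intratumoral T-cell infiltration (proxied by CD3, the pan-T-cell marker
complex) influences prognosis and response to immunotherapy in glioblastoma,
but measuring it requires tissue. `cd3radiomics` implements a fully
non-invasive alternative: quantify the heterogeneity of the tumor on routine
MRI (T1 post-contrast and T2-FLAIR) with texture statistics, screen those
statistics for geometric robustness and for association with CD3 activity,
and fit a compact symbolic-regression classifier of binary infiltration
status. Every stage — synthetic data, preprocessing, the 86-feature panel,
robustness screening, all-relevant selection, the classifier, and the
evaluation statistics — is exposed as a tested function, and the whole chain
runs end-to-end on synthetic phantoms so that no patient data are required to
exercise or validate it.

## Preprocessing

Volumes are assumed bias-field corrected upstream (the reference workflow
used N3 with signal threshold 1.0, field distance 50 mm, kernel FWHM 0.15;
this package does not reimplement it). The chain is then:

1. **NAWM normalization** (`normalize_to_nawm`). Tumor intensities are
   divided by the mean intensity of a contralateral normal-appearing white
   matter mask, making intensities unitless ratios and removing the
   scanner-dependent scale. The NAWM mean of the output is exactly 1; the
   operation is invariant to positive rescaling of the input.
2. **Isotropic reslicing** (`reslice_isotropic`). Multi-site MRI arrives with
   anisotropic voxels (slice thickness up to several mm); texture offsets
   assume comparable physical distance per voxel step. Intensities are
   trilinearly interpolated and masks nearest-neighbor resampled onto a 1 mm
   isotropic grid. Grids are half-voxel-centered, axis order (x, y, z); the
   physical extent is preserved within one voxel, and mask volume within a
   few percent.
3. **Quantization** (`quantize`). In-mask intensities are binned into G = 8
   equal-width levels over the per-ROI min-max range
   (`level = 1 + floor(G (x - min)/(max - min))`, max clamped to G; a
   constant ROI maps to level 1). Equal-width min-max binning is the standard
   radiomics dialect and is invariant to positive affine intensity
   transforms. The stage order is normalize, then reslice, then quantize.
   Equal-probability binning would destroy the gray-level-dependent features
   (every level would be equally occupied), so it is not offered.

## The 86-feature panel

Per modality, 43 features: 6 histogram statistics of the quantized levels
(mean, variance, skewness, kurtosis, entropy, uniformity), 19 gray-level
co-occurrence features, 5 neighborhood gray-tone difference features, 11
gray-level size-zone features, and 2 regional features (tumor volume in mm³
and total normalized intensity). Conventions that matter:

- **Kurtosis** is the Pearson (non-excess) fourth standardized moment
  `m4 / m2^2` of population moments (normal = 3), constant throughout.
- **Co-occurrence** uses distance 1 over the 13 unique 3D directions,
  counting only pairs with both voxels in the mask, accumulated
  symmetrically and *pooled* (summed) across directions before
  normalization. Pooling keeps the panel at 19 features rather than 19 × 13
  and is insensitive to direction ordering. The 19 are the 13 Haralick
  features plus autocorrelation, cluster shade/prominence/tendency,
  dissimilarity and maximum probability; entropies are base 2.
- **NGTDM** uses the 26-neighborhood restricted to in-mask voxels; voxels
  with no in-mask neighbor are excluded. The five Amadasun-King features
  follow the published formulas.
- **GLSZM** zones are maximal 26-connected components of equal gray level
  ("3D zones"); 26-connectivity is the standard radiomics reading. Zone
  sizes always satisfy `sum_ij j P(i,j) = N_voxels`, which is asserted in
  the tests.
- **Degenerate guards.** A constant ROI has undefined co-occurrence
  correlation and infinite NGTDM coarseness; the package reports correlation
  1 (a flat region is perfectly self-similar), caps coarseness at 1e6, sets
  skewness/kurtosis to 0 at zero variance, and flags such outputs with a
  `degenerate` attribute instead of propagating non-finite values. All 86
  features are finite by contract.

Feature names are `{modality}_{family}_{feature}` (e.g.
`t1post_glszm_small_zone_emphasis`); the registry ships as
`inst/extdata/feature_registry.json` and via `feature_names()`.

All three matrix families are cross-checked against naive enumeration
oracles (explicit pair/neighborhood/zone loops in R) on hundreds of random
small arrays in the test suite, and all 41 texture features are verified
translation invariant.

## Robustness screening

Because hand-drawn tumor contours are imprecise, a feature is only useful if
it survives plausible contour perturbation. Eight canonical perturbations of
the (resliced, 1 mm) tumor mask are applied per patient: in-plane translation
by 2 voxels (horizontal, and horizontal+vertical), axial rotation by 1° and
5° about the mask centroid (nearest-neighbor re-rasterized), random boundary
jitter with sd 0.1 and 0.5 voxels, and radial dilation and erosion by one
voxel. Jitter is implemented at voxel level: each in-plane boundary voxel is
displaced along its local outward normal by `N(0, sd)` plus a uniform
sub-voxel offset (the true contour sits somewhere inside the boundary voxel)
and the sum is rounded — this reproduces what re-rasterizing a jittered
polygon does to the voxel grid while remaining robust for non-convex masks,
which is why it was preferred over explicit contour-polygon manipulation.

Features are re-extracted under the original and all 8 perturbed masks (the
normalized, resliced volume is fixed) and screened by the intraclass
correlation across the 9 versions: one-way random-effects ICC(1,1),
`(MSB - MSW) / (MSB + (k-1) MSW)`, retaining features with ICC ≥ 0.6.
ICC(3,1) is available as an option. Negative estimates are clamped to 0 in
the report (flagged); identical measurements define ICC = 1. Robustness is
assessed per modality — a feature must be stable in its own modality only,
the less demanding reading of an ambiguous rule, chosen because the two
modalities have genuinely different contrast mechanisms.

## All-relevant feature selection

Association with the continuous CD3 z-score is assessed by a shadow-feature
procedure: each round appends a freshly permuted copy of every feature, fits
a random-forest regressor (ranger, 500 trees, z-scored permutation
importance), and counts a "hit" for each undecided feature whose importance
exceeds the *maximum* shadow importance. Accumulated hits are tested against
Binomial(rounds, 1/2) two-sided at α = 0.01 with Bonferroni correction over
the panel; features still undecided after 100 rounds are resolved by
comparing median importance with the median max-shadow importance. Unlike
minimal-subset selectors this confirms *every* feature carrying signal,
including correlated duplicates — the property the tests verify directly.

Two design points were settled empirically during development. All features
and all shadows stay in the forest every round: dropping rejected features
(and their shadows) shrinks the shadow reference until features with
persistent spurious sample correlations beat it, which inflated the
false-confirmation rate on pure-noise outcomes. And importance is z-scored
(scaled by its standard error across trees), which further stabilizes the
max-shadow comparison; both choices match the behavior of the reference R
implementation of the algorithm.

Confirmed features are then pruned for redundancy: a greedy pass in
descending mean importance keeps a feature iff its absolute Pearson
correlation with every kept feature is below 0.6, so the retained set has all
pairwise |r| < 0.6 and keeps the more important member of any correlated
pair (the tie-break the source analysis leaves unstated).

The published six-feature panel (T1-post kurtosis, NGTDM contrast, and four
size-zone features) ships frozen as a packaged JSON resource
(`paper_feature_set()`) so the classifier can run without re-selection. When
CD3 is a combination of several markers' z-scores, their mean is used as the
single continuous outcome (configurable).

## The classifier

`fit_symbolic()` fits a genetic-programming symbolic regression: expression
trees over `{+, -, ×, protected ÷}` with the selected features and ephemeral
constants in [-1, 1] as terminals. Protected division returns 1 when the
denominator's magnitude is below 1e-9, so every expression is finite on
finite inputs. Defaults: population 500, 50 generations, depth ≤ 6,
tournament size 3, subtree crossover 0.8, subtree mutation 0.15, one elite,
ramped initialization at depths 2-4, and lexicographic parsimony pressure
(selection ties on fitness resolve toward the smaller tree — rank-based AUC
on small training sets ties often, and without bloat control the engine
drifts toward needlessly large, overfit expressions). Fitness is the *training AUC* of the
expression's continuous output (rank-based, ties ½) rather than squared
error, because the endpoint is binary classification; the continuous score
also feeds the Spearman concordance analysis. The decision threshold is the
Youden-optimal (max sensitivity + specificity - 1) point on the training
ROC, ties broken toward the smallest threshold; it is chosen on training
data only, and the fit interface never sees test outcomes. Fits are
deterministic given a seed. A transparent logistic-regression comparator
(`fit_logistic`) exposes the same interface and return class.

Cohorts are split 50/50 at random (training gets the odd patient), redrawn
up to a cap if a class is missing from either half, with a Kruskal-Wallis
balance report per clinical/volumetric variable.

## Evaluation statistics

- AUC in the Mann-Whitney form (ties ½), exhaustively checked against a
  brute-force pairwise oracle.
- AUC confidence intervals by stratified bootstrap (resampling within each
  class, percentile interval, B = 2000).
- Confusion-matrix metrics with "high infiltration" as the positive class:
  accuracy with two-sided exact Clopper-Pearson 95% CI (`binom.test`),
  sensitivity, specificity, and the classifier false discovery rate
  FP/(TP+FP) (flagged undefined when nothing is predicted positive).
- Spearman rank concordance between continuous scores and continuous CD3,
  asymptotic two-sided p (uniform treatment of ties).
- Covariate adjustment by a single multivariate linear model of continuous
  CD3 on age, sex, KPS, both modalities' tumor volumes and total intensities,
  and the model predictions, reporting one p-value per term
  (logistic-on-binary available since the source analysis is ambiguous);
  rank-deficient designs are rejected with the aliased columns named.
- Paired bootstrap comparison of two models' AUCs on the same cases
  (two-sided normal p from the bootstrap SD of the AUC difference; identical
  scores give p = 1).

## The synthetic cohort generator

The phantom emulates exactly what the pipeline consumes: two co-registered
modality volumes on an anisotropic grid (0.9 × 0.9 × 3.0 mm by default, so
reslicing is genuinely exercised), an ellipsoidal tumor, a larger
FLAIR ROI (the tumor ellipsoid scaled by a per-patient edema margin factor of
1.05-1.25), and a disjoint spherical NAWM reference. Tumor texture is a
Gaussian random field — white noise convolved with a Gaussian kernel of
stated correlation length, normalized to unit variance analytically —
scaled by an amplitude, plus a rim-enhancement term
`rim_amp · exp(-d²/(2 w²))` in the distance d (mm) to the ellipsoid surface
(T1 only by default, emulating ring enhancement), plus i.i.d. voxel noise.
The field is applied inside the tumor ROI only; the NAWM region stays flat
plus noise so the normalization denominator is stable and positive. Default
intensities (tumor base 300 vs NAWM 200 on T1; 420 vs 250 on FLAIR; noise
sd 15-20) give a realistic contrast and SNR regime. Tumor semi-axes default
to 16 × 14 × 12 mm, scaled per patient by a uniform 0.85-1.1 size factor
(independent of CD3), so volumetric covariates vary about two-fold across a
cohort; with ~17,000 tumor voxels at 1 mm, texture statistics are estimated
stably — a deliberate design choice, since much smaller phantoms leave too
little signal in the panel for any downstream method to recover.

Per-patient texture parameters are drawn uniformly (T1 correlation length
1.5-6 mm — fine to coarse; amplitudes and rim strength vary moderately), and
the continuous CD3 z-score is a linear link on *standardized true
parameters* plus Gaussian noise; the default is the standardized T1
correlation length plus N(0, 0.45) noise, dichotomized at 0. The noise level
makes the latent class separation imperfect (ideal-observer AUC ≈ 0.93),
emulating a biomarker with realistic residual noise. Age, sex and KPS are
drawn independently of CD3, so covariate-adjusted analyses have a known
null. Everything is a pure function of the cohort seed.

**A percolation caveat discovered during development.** At G = 8 with
26-connectivity in 3D, the level sets of a fine-scale random field lie above
the site-percolation threshold and merge into one giant zone per occupied
level. In consequence, *increasing* the field correlation length *increases*
small-zone emphasis and NGTDM contrast but *decreases* large-zone emphasis —
the opposite of the 2D intuition that coarse texture means larger zones.
This inversion is robust across noise levels and rim settings; the
monotonicity property of the generator is therefore stated and tested in
these verified directions. For selection and classification only the
monotone association matters, not its sign.

**What the phantom does not emulate:** anatomy, bias fields, registration
error, multi-site intensity distributions, or the empirical intensity
histograms of real glioblastoma (the source data give no distributional
description to match). Passing the end-to-end tests therefore demonstrates
that the pipeline recovers a known texture-CD3 link through the full
preprocessing/extraction/selection/classification chain — not that it would
achieve any particular accuracy on clinical data.

## Problem sizes in the test and acceptance suites

The oracle fuzz uses 200 random arrays up to 5×5×5 voxels; the end-to-end
recovery experiment uses 10 cohorts of n = 150 phantoms (roughly the scale
of the source cohorts: 79 + 69 patients), asserting that coarseness features
are confirmed in ≥ 8/10 cohorts and held-out AUC exceeds 0.8 in ≥ 8/10; the
pipeline smoke test uses a 20-patient cohort. These sizes were chosen so the
full suite runs comfortably on a laptop while keeping the binomial margins
of the recovery assertions meaningful.

## Known limitations

- The exact identities of the source panel's 19 co-occurrence and 6
  histogram features are not published; the counts are fixed and the
  identities documented here. Of the published selected features only NGTDM
  contrast depends on family identity, so the headline pipeline is
  insensitive to this list's tail.
- The ICC form (ICC(1,1)) and the Boruta and GP hyperparameters are
  documented defaults; the source analysis does not state its choices.
- Rotations and translations act in-plane (the perturbations are described
  2D-style); through-plane contour uncertainty is represented only by
  dilation/erosion.
- Test-retest (re-scan) robustness and inter-rater segmentation variability
  are out of scope.
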