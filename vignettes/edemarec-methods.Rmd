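---
title: "Methods: locating recurrence-prone peritumoral edema from ADC histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating recurrence-prone peritumoral edema from ADC histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edemarec)
```

## The problem

Glioblastoma recurs preferentially inside the T2-FLAIR-hyperintense edema
that surrounds the resected tumor, but conventional imaging cannot show
*which* part of that edema is already micro-infiltrated.  On an apparent
diffusion coefficient (ADC) map the two tissue states pull in opposite
directions: vasogenic edema is free-water-rich (high ADC), while
infiltrating tumor cells restrict diffusion (low ADC).  `edemarec`
implements an analysis built on that contrast.  The pre-recurrence edema of
each case is split retrospectively, after rigid registration of the
follow-up scan, into

* `subedema_rec` — the edema voxels later overlapped by recurrent tumor, and
* `subedema_no_rec` — the remainder,

and eight first-order ADC histogram statistics are compared between the two
sub-volumes.  The discriminative statistic is the **max/mean ADC ratio**
(`ratio_maxi_mean`): the maximum ADC of a region divided by its mean ADC.
A region dominated by micro-infiltration has both a depressed mean and few
free-water extremes, so its ratio behaves differently from purely vasogenic
edema.  A fixed ratio cutpoint of 2.408 (a published ROC cutpoint for this
statistic) drives the tile-level location predictor.

## Sub-volume construction

Recurrent tumor is contoured on the follow-up scan, which is misaligned
with the pre-recurrence anatomy.  A 6-degree-of-freedom rigid transform
maps points of the pre-recurrence grid into the follow-up volume
(`apply_rigid()` resampling convention: `out(x) = input(T(x))`); masks are
resampled with linear interpolation and re-binarised at 0.5, which is
unbiased for half-voxel shifts.  On the common grid the partition is plain
set algebra: `subedema_rec = edema ∩ recurrent tumor`,
`subedema_no_rec = edema \ recurrent tumor`.  The partition is checked to
be disjoint and exhaustive on every labelling.  Cases whose recurrence does
not touch the edema are flagged and excluded downstream, mirroring the
inclusion criterion that recurrence must fall at least partly within the
original edema.  The pre-recurrence tumor mask is *not* subtracted from the
edema: the two structures are contoured as disjoint, and inputs are
validated for disjointness.

Two phrasings of `subedema_rec` circulate (remainder-of-edema versus
overlap-with-recurrent-tumor); they coincide only when recurrence stays
inside the edema.  The overlap definition is implemented because it is the
operationally precise one.

## Registration

`estimate_rigid()` maximises normalised cross-correlation (mean-squares is
available) over Euler angles (ZYX order) about the volume centre plus a
translation, using a deterministic multi-start scheme: a coarse grid of
angle starts with the translation initialised from the intensity
centre-of-mass offset, Nelder–Mead refinement of the best starts on a
stride-2 lattice, and a full-resolution polish.  Both images are Gaussian
pre-smoothed (sigma 1 voxel by default).  The smoothing matters for more
than noise robustness: comparing a sharp fixed image against an
interpolation-smoothed moving image biases the optimum by a fraction of a
voxel at piecewise-constant boundaries, and smoothing both sides
symmetrises the edge profiles and removes that bias.  The pipeline accepts
precomputed transforms (serialised as a plain-text 4x4 homogeneous matrix,
the ITK layout) wherever an external registration is preferred; tests
exercise known ground-truth transforms.

## Histogram features

`extract_features()` computes, over the voxels of a region of interest:
mean; sample standard deviation (n−1); maximum; minimum; median (average of
the two middle order statistics for even n); skewness `g1 = m3/m2^1.5`;
kurtosis `m4/m2^2`; and the max/mean ratio.  Kurtosis is reported
**non-excess** by default — the convention of common radiomics toolkits —
with an `excess_kurtosis` switch, since either convention is defensible and
reported values in the literature rarely say which was used.  Skewness and
kurtosis are reported as missing (`NA`), never as 0, when the region has
fewer than 3 voxels or zero variance; regions of fewer than 2 voxels are
rejected.  Features are computed on the ADC map resampled to the T1
analysis grid, not at native DWI resolution.

## The statistical stage

Each case contributes **two rows** (one per sub-volume) with
`label ∈ {rec, no_rec}`; this is the only reading under which a ROC over
sub-volumes is defined.  The pairing is used by the Wilcoxon stage and
deliberately ignored by the regression models.

* **Paired Wilcoxon** per feature: signed-rank statistic on nonzero
  differences, mid-ranks for tied magnitudes; exact two-sided p by
  enumeration of all 2^m sign vectors for m ≤ 12 without ties, otherwise
  the normal approximation with tie and continuity corrections.
* **Spearman correlation** (feature against sub-volume size): Pearson
  correlation of mid-ranks; exact permutation p for n ≤ 10 (full n!
  enumeration, streamed in blocks at n = 10), t approximation above.
* **Lasso screen** (`lasso_logistic_path()`): L1-penalised logistic
  regression solved by cyclic coordinate descent inside an IRLS loop
  (implemented in C++), features standardised internally, intercept
  unpenalised.  The grid is 100 log-spaced values from `lambda_max` (the
  smallest penalty with an all-zero solution, computed from the null-model
  score) down four decades.  KKT conditions are verified along the path.
  `lambda_min` minimises 10-fold cross-validated binomial deviance; folds
  are stratified by label and seeded.  Separation at small lambda truncates
  the path with a warning.
* **Forward stepwise logistic regression**
  (`forward_stepwise_logistic()`): candidates are the lasso survivors;
  entry by smallest likelihood-ratio p while p < 0.05 (`alpha_entry`,
  conventional and configurable); the final model is refit by IRLS to
  convergence and reported with Wald p-values and odds ratios.  The exposed
  effect sizes are odds ratios — a logistic model has no hazard ratios.
* **ROC** (`roc_analysis()`): empirical curve over all distinct cutpoints;
  AUC as the tie-corrected Mann–Whitney statistic `U/(n1·n0)` (equal to the
  trapezoidal area); Youden cutpoint maximising sensitivity + specificity −
  1 with ties broken toward higher specificity; orientation auto-chosen so
  the training AUC is ≥ 0.5, or fixed by the caller.
* **Comparison classifiers**: RBF-kernel SVM and random forest with
  package-default settings, scored by pooled out-of-fold probabilities
  under the same seeded stratified CV.  Their contract is seed
  reproducibility, not specific AUC values.

All p-values are two-sided and no multiplicity correction is applied, which
matches the analysis style this pipeline reproduces.

## The tile heatmap

On the axial slice with the largest tumor area among slices containing
edema (ties to the lowest index), the edema is partitioned into square
tiles of 2, 2.5 or 3 voxels per side, anchored at the corner of the edema
bounding box.  Fractional sizes are realised exactly on a 2x bilinearly
upsampled grid (2.5 voxels → 5 fine cells).  A tile is evaluated iff at
least 50% of its area lies inside the edema.  The per-tile statistic is

> (maximum ADC over the tile's edema voxels) / (mean ADC over *all* edema
> voxels on the slice),

and tiles with a value **below** the threshold (default 2.408) are
predicted recurrence-prone.  Two deliberate design choices need stating:

* **The denominator is the whole-ROI mean, not the within-tile mean.**  A
  4-voxel tile's max/mean is bounded close to 1 and could essentially never
  cross a cutpoint of 2.408; dividing the tile max by the slice-ROI mean is
  the only reading under which a ROI-scale cutpoint is operative at tile
  scale.
* **Direction.**  The decision rule marks *low*-ratio tiles as
  recurrence-prone (`below_positive`), consistent with recurrence arising
  where free-water extremes are absent.  The opposite account — locally
  elevated maxima inside infiltrated tissue — also appears in the
  literature, so the direction is a configurable parameter rather than a
  hard-coded fact.

Voxel-level evaluation against a ground-truth recurrence mask restricts to
edema voxels on the slice; non-evaluated tiles count as predicted negative.
Accuracy is `(TP+TN)/total` and overlap is the Dice coefficient.
Rendering (`render_heatmap()`) alpha-blends a viridis colour map over the
grayscale background and is byte-deterministic; PNG is used for the raster
because its encoding is reproducible across runs.

## The phantom generator

Real ADC maps with recurrence follow-up cannot be redistributed, so every
stage is exercised on seeded synthetic phantoms (`phantom_spec()`,
`generate_phantom()`, `generate_cohort()`).  The geometry is deliberately
analytic — a spherical tumor core, a spherical-shell edema, and an angular
infiltration wedge (two lobes by default, emulating multifocal
micro-infiltration) — so ground-truth masks are exact.  A known rigid
misalignment (default 3° about z plus 2 mm translation) moves the
post-recurrence volume onto its own grid; the recurrent tumor equals the
pre-recurrence tumor united with the infiltrated wedge.

Intensities are mixtures of normal components (units 10^-6 mm^2/s):
background 750±50, tumor 600±80, vasogenic shell base 1500±150,
infiltrated base 1250±200.  Under the default `rec_lower_ratio` direction
the non-infiltrated shell additionally contains a free-water-like
high-ADC admixture (55% of voxels at mean 8400), and the infiltrated wedge
a 10% admixture of low-ADC cellular foci at half its base mean;
`rec_higher_ratio` swaps the two admixtures.  These composition defaults
were **calibrated at design time, by closed-form analysis plus a
slice-level simulation**, to a single requirement: the fixed published
cutpoint 2.408, applied to tile-max over slice-ROI-mean, must actually
separate infiltrated from vasogenic tiles, with 2x2 tiles outperforming
3x3 tiles through their finer boundary quantisation.  That forces the high
component well above physiological free water (about 3000): with a
substantial high-ADC fraction `f` in the shell, the tile rule is only
operative when the high component exceeds `2.408` times the ROI mean that
it itself inflates, which has no solution at physiological magnitudes.
The phantom is therefore a *structural* emulation — correct geometry,
correct decision topology, exact ground truth — and not a radiometric one.

What the phantoms do not emulate: anatomy, bias fields, EPI distortion,
partial-volume gradients, or the inter-feature correlation of real
histogram statistics.  Two consequences are worth knowing.  First, on
noisy phantoms the ROI-level max/mean ratio of the two sub-volumes is
nearly equal, because the maximum of thousands of Gaussian draws is
dominated by the noise tail; the ratio's ROI-level direction contract is
therefore stated (and tested) on noiseless phantoms, while the tile-level
rule — which uses local maxima over 4–9 voxels — carries the location
signal under noise.  Second, passing phantom tests demonstrates
correctness of the machinery, not clinical performance.

For model-selection experiments a feature-level generator
(`simulate_feature_cohort()`) bypasses images entirely: eight independent
features on plausible natural scales with a standardised location effect
(default 1.2 SD) planted on the ratio only, 32 cases of two rows each.
Independence across features and rows is the cleanest reading of "no other
signal"; it also makes the selection task *harder* than correlated real
data, because the cross-validated-minimum lambda is a liberal screen and
noise features that survive it carry selection-inflated significance into
the stepwise stage.

## Numerical choices and problem sizes

* Voxel indexing is 0-based in physical-coordinate computations; the NIfTI
  affine carries `direction %*% diag(spacing)` with the origin in its
  fourth column.  Resampling fill value is 0; regions of interest are
  required to lie inside the valid field of view.
* Mask binarisation after interpolation is fixed at 0.5.
* Lasso: coordinate-descent tolerance 1e-10, IRLS weights floored at 1e-6,
  probabilities clamped at 1e-8; KKT residuals are checked to 1e-6.
* Stepwise refit: `glm` with epsilon 1e-10.
* Exact-test branches: Spearman n ≤ 10, Wilcoxon m ≤ 12 without ties.
* Ties: Youden cutpoints break toward specificity; slice selection toward
  the lower index; mid-ranks everywhere.
* All randomness descends from a single seed through named substreams
  (cohort generation, CV folds, classifiers), so identical configurations
  reproduce bit-identical results.
* Default problem sizes: 64x64x32 phantoms at 2 mm isotropic spacing;
  unit tests run on 32x32x18 grids; simulation-based properties use 50–100
  seeded replicates and cohorts of 32 cases.  These sizes were chosen so
  the full suite runs comfortably on a laptop-class single core.

## Known limitations

* The whole-ROI-mean tile denominator, the tile anchoring and the ≥50%
  area rule are design decisions; other readings of a tile-based ratio map
  are possible and would shift the operating point of the fixed cutpoint.
* The lasso-then-stepwise chain, run at its conventional settings
  (CV-minimum lambda, entry at 0.05), admits a spurious noise feature in a
  non-negligible fraction of planted-effect replicates; this is a property
  of the method itself (a liberal screen followed by selection-biased
  entry tests), and the package reports it honestly rather than tuning
  around it.
* Registration is mono-modal rigid with two metrics; no deformable or
  multi-resolution-pyramid registration is provided.
* The predictor is slice-based, as is the analysis it implements; a
  volumetric extension would be a non-default variant.
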