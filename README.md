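# edemarec

Predicting which part of the peritumoral edema around a resected
glioblastoma is at high risk of harbouring tumor recurrence, from
first-order histogram features of the apparent diffusion coefficient (ADC)
map.

Glioblastoma recurs preferentially inside the T2-FLAIR-hyperintense edema
surrounding the enhancing tumor, yet conventional imaging cannot delineate
the micro-infiltrated part of that edema — a real problem when choosing
surgical margins and radiotherapy target boundaries.  `edemarec` is aimed
at imaging researchers who want a tested, fully seeded reimplementation of
an ADC-histogram approach to that question: registration-based sub-volume
construction, per-region histogram statistics, a lasso + stepwise logistic
modelling stage with ROC thresholding, and a tile-based heatmap that
localises the recurrence-prone region on a single slice.  Because clinical
ADC maps with recurrence follow-up cannot be redistributed, the package
ships a phantom generator that produces whole cohorts with exact ground
truth, so every stage is testable offline.

## The method in brief

For each case, the pre-recurrence edema *E* is partitioned after rigid
registration of the follow-up scan into

* `subedema_rec` = *E* ∩ (recurrent tumor), and
* `subedema_no_rec` = *E* \ (recurrent tumor).

Eight first-order statistics are computed per sub-volume from the ADC map:
mean, SD, max, min, median, skewness *g₁ = m₃/m₂^{3/2}*, kurtosis
*m₄/m₂²*, and the discriminative statistic

> **Ratio-maxiADC/meanADC** = max(ADC) / mean(ADC) over the region.

Features are screened by L1-penalised logistic regression (coordinate
descent; λ chosen by seeded, stratified 10-fold cross-validation at
minimum deviance), survivors enter a forward stepwise logistic regression
(likelihood-ratio entry at α = 0.05), and the model is summarised by an
empirical ROC with a Youden cutpoint (AUC = Mann–Whitney *U*/(n₁n₀)).
For location prediction, the analysis slice is tiled in 2×2, 2.5×2.5 or
3×3-voxel units; each tile is scored by (tile max ADC)/(slice-ROI mean
ADC) and tiles **below** the cutpoint (default 2.408) are flagged as
recurrence-prone.

## Worked example

```r
library(edemarec)

# a synthetic case: tumor core, edema shell, known infiltrated wedge,
# and a misaligned post-recurrence volume
cs <- generate_phantom(phantom_spec(seed = 42))
#> <phantom_case> case_01: 64x64x32 voxels, tumor 2176 vox, edema 9360 vox (infiltrated 4680)

# bring the recurrent tumor mask onto the pre-recurrence grid and
# partition the edema
rec <- transform_mask(cs$tumor_rec_native, invert_rigid(cs$misalignment),
                      vol_grid(cs$edema_pre))
lab <- define_subvolumes(cs$edema_pre, rec)
#> <subvolume_labeling> edema 9360 vox = rec 4676 + no_rec 4684

extract_features(cs$adc_pre, lab$subedema_rec)
#> <histogram_features> n=4676 mean=1179.3 sd=283.5 max=1973.3 min=51.8 ratio=1.673
extract_features(cs$adc_pre, lab$subedema_no_rec)
#> <histogram_features> n=4684 mean=5232.5 sd=3442.7 max=8877.0 min=624.2 ratio=1.697

# tile heatmap on the slice with the largest tumor area
sl <- select_slice(cs$tumor_pre, cs$edema_pre)           # 16
hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2)
#> <tile_heatmap> slice 16, 2.0-voxel tiles: 104 evaluated, 55 predicted positive (threshold 2.408, below_positive)
evaluate_prediction(hm, cs$truth_infiltration, cs$edema_pre)
#> voxel accuracy 0.958, dice 0.958
```

The sub-volume partition recovered the planted infiltration (4676 of 4680
wedge voxels), and thresholding the 2×2-voxel tile ratios at 2.408 located
it on the analysis slice with Dice 0.96 against ground truth.  The cohort
demographics helper reproduces the reference study population exactly:

```r
summarize_cohort(read_demographics())
#> <cohort_summary> n=32 (16 male / 16 female), mean age 50.6 years
```

A full cohort run — feature table, paired Wilcoxon and Spearman reports,
lasso path, stepwise model, ROC and SVM/random-forest comparison AUCs —
is one call: `run_cohort_analysis(run_config(n_cases = 32, seed = 1))`.

A thin command-line front end (`inst/cli/edemarec.R`) exposes `simulate`,
`analyze`, `heatmap` and `summarize` subcommands over NIfTI inputs, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","edemarec.R",package="edemarec"))')" \
  heatmap --adc adc.nii.gz --edema edema.nii.gz --tumor tumor.nii.gz \
  --tile-size 2 --threshold 2.408 --out heatmap.png --mask-out pred.nii.gz
```

Labelmap exports code `1 = subedema_rec`, `2 = subedema_no_rec`.

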