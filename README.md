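# amypet

Neuropathology-anchored amyloid-PET classification on synthetic phantom
cohorts.

## What this package is for

End-of-life amyloid-PET studies validate image classification against
autopsy. Two neuropathological Standards of Truth are used: binarized
CERAD neuritic plaque density from Bielschowsky silver staining (abnormal
when any regional mean density score exceeds 1.5) and the dichotomized
amyloid (Thal) phase (0–2 vs 3–5). `amypet` implements the full analysis
pipeline built on those ground truths, for researchers who want a tested,
reusable implementation of each stage:

* **Balanced-resampling linear-SVM ensembles** — in each of 50 repeats the
  majority class is subsampled to the minority size, leave-one-out
  cross-validation is run within the balanced set, surplus cases are scored
  by the full balanced-set model, and the repeat hyperplanes are averaged
  into a mean classifier `(w̄, b̄)`. The soft-margin dual (`C = 1`, linear
  kernel, no standardization) is solved exactly by an active-set quadratic
  program with KKT refinement.
* **Distance-to-hyperplane scoring** — the signed geometric distance
  `d = (w·x + b)/‖w‖`, with negative `d` meaning amyloid-positive; a
  continuous measure of classification evidence.
* **Top-weight voxel selection** — the 10% of brain voxels with the
  largest absolute mean feature weights define "select" classifier
  variants.
* **SUVR and Centiloid quantification** — cerebellar-GM-referenced SUVR,
  composite-VOI means, and the affine Centiloid conversions
  `CL = 127.6·SUVR_comp − 149` (MRI-assisted) and
  `CL = 210.49·SUVR_comp − 250.13` (PET-only), plus least-squares
  recalibration.
* **PET amyloid staging** — the four-level cortex/caudate threshold scheme
  and the three-level cortical/striatal read scheme, with threshold-based
  read surrogates.
* **Inference** — ROC with Youden-maximized cut-offs, Pearson/Spearman
  association, Dunn & Clark's z for two overlapping dependent correlations,
  Welch ANOVA with Bonferroni-corrected pairwise Welch t-tests, and
  tie-exact Kruskal–Wallis / Mann–Whitney tests.
* **A synthetic phantom module** — deterministic atlas plus cohort
  generators reproducing the published end-of-life cross-table (29/72
  Bielschowsky-negative/positive, 22/79 phase-low/high, 7 discordant
  cases) and an asymptomatic-like cohort with a continuous, right-skewed
  amyloid-burden distribution, so the whole pipeline runs and is tested
  without patient data.

The methods vignette (`vignettes/amypet-methods.Rmd`) documents the models,
conventions and numerical choices in detail.

## Worked example

Generate an end-of-life-like cohort on a small grid, train a
balanced-subsample ensemble against the plaque-density ground truth, and
relate the distance to the hyperplane and the Centiloid scale to the
neuropathology:

```r
library(amypet)
atlas <- generate_atlas(c(20, 24, 20), 4)
eol   <- generate_cohort(atlas, "table1", signal_model(), master_seed = 42)
tab   <- label_cohort(eol)
table(bss = tab$bss_label, phase = tab$phase_label)
#>           phase
#> bss        high low
#>   abnormal   72   0
#>   normal      7  22

X <- feature_matrix(cohort_suvr(eol), atlas_brain_mask(atlas))
ens <- balanced_loo_ensemble(X, tab$bss_label == "abnormal", n_repeats = 10,
                             master_seed = 42,
                             feature_mask = atlas_brain_mask(atlas))
ens
#> <ensemble_result> 10 repeats, 29 cases per balanced class
#>       metric  mean    sd ci_lower ci_upper
#>  specificity 89.31 3.019    87.15    91.47
#>  sensitivity 85.00 2.839    82.97    87.03
#>     accuracy 86.24 2.308    84.59    87.89
```

Every repeat balances the 72 abnormal against the 29 normal cases; the
summary is the mean/SD/95% CI of the per-repeat rates over the whole
cohort. The mean classifier's signed distances fall with advancing
amyloid phase (negative = classified amyloid-positive):

```r
d <- apply(X, 1, function(x) distance_to_hyperplane(ens$mean_classifier, x))
round(tapply(d, tab$amyloid_phase, median), 2)
#>     0     1     2     3     4     5
#>  1.69  1.69  1.69 -0.39 -1.09 -1.98

suvr_comp <- vapply(cohort_suvr(eol), composite_suvr, numeric(1), atlas = atlas)
cl <- suvr_to_centiloid(suvr_comp, centiloid_calibration("pet_only"))
roc_youden(cl, tab$phase_label == "high")
#> <roc_result> AUC = 98.8%, Youden cut-off = 119.3 (spec 100.0%, sens 93.7%)
```

The Centiloid values here live on the phantom's own signal scale; the ROC
machinery, not the particular cut-off, is the point of the example.
`run_study()` performs the complete analysis — training the four
original/select × BSS/phase classifiers at full size, transferring them to
the asymptomatic-like cohort, cross-ground-truth evaluation and staging —
from a single configuration list (`default_study_config()`), writing
per-subject CSVs and a statistics JSON if an output directory is given. A
thin command-line wrapper lives at `inst/scripts/amypet.R`.

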