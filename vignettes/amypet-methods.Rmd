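---
title: "Neuropathology-anchored amyloid-PET classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuropathology-anchored amyloid-PET classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypet)
```

## The scientific problem

Amyloid PET is validated against autopsy: in end-of-life cohorts, scans
acquired near death can be compared with the neuropathological ground truth
established post mortem. Two such Standards of Truth are in common use. The
first binarizes the modified CERAD neuritic plaque density from Bielschowsky
silver staining (BSS): a case is *abnormal* when at least one regional mean
neuritic plaque density score exceeds 1.5 on the 0–3 scale (strictly; a
score of exactly 1.5 everywhere is still negative). The second dichotomizes
the hierarchical amyloid (Thal) phase, grouping phases 0–2 (held to be below
the in-vivo detection limit of amyloid PET) against phases 3–5.

This package implements, end to end, a classification analysis anchored to
those two ground truths: linear support-vector-machine (SVM) ensembles
trained on voxelwise SUVR images of an end-of-life-like cohort, transfer of
the trained classifiers to an asymptomatic-like cohort quantified on the
Centiloid scale, threshold-based PET amyloid staging, and the associated
inferential toolkit. Because the real cohorts are not public, the package
ships a synthetic phantom module that emulates their statistical structure,
so every stage is exercised and tested without any patient data.

## The classification procedure

### Balanced-subsample leave-one-out ensembles

The end-of-life-like cohort is imbalanced (29 BSS-negative vs 72
BSS-positive; 22 phase-low vs 79 phase-high). Training a single SVM on
imbalanced data biases the hyperplane, so the procedure balances by
resampling: in each of 50 repeats, the majority class is randomly subsampled
(uniformly, without replacement) down to the minority-class size — 29 cases
per class for the BSS truth, 22 for the phase truth. Within the balanced
set, leave-one-out (LOO) cross-validation is run: every case is held out
once and predicted by an SVM fit on the remaining balanced cases. The
surplus majority-class cases excluded from the balanced set are predicted by
the model fit on the full balanced set, so each repeat predicts every cohort
case exactly once. Specificity, sensitivity and accuracy are computed per
repeat over the whole cohort and summarized as mean, SD, and a normal-theory
95% CI of the mean (`mean ± t(0.975, 49) · SD/√50`; the CI construction is
a package convention and is labelled in the output).

A *mean classifier* is formed by componentwise averaging of the 50 repeat
models' weight vectors and biases, raw and un-normalized; with a common box
constraint the weight scales are comparable across repeats, and averaging
raw weights is the simplest reading of a "mean classifier". The 10% of
brain-mask voxels with the largest absolute mean weights (ties broken by
ascending linear voxel index; the count is `round(0.10 · n)`) define a
reduced feature set, and the whole ensemble procedure is re-run on that
selection with fresh subsample seeds, yielding the four classifiers
*original/select × BSS/phase*.

### The linear SVM and its solver

Each fit is a soft-margin linear C-SVM with `C = 1` and no feature
standardization. With far more voxels than cases the dual problem is tiny
(at most 58 variables) and strictly convex, so it is solved *exactly*: the
dual quadratic program is assembled in package code on a precomputed linear
Gram matrix and solved with the Goldfarb–Idnani active-set method
(`quadprog::solve.QP`), followed by an exact KKT refinement that removes the
numerical regularization bias (a ridge of `1e-10 × mean(diag(K))` keeps the
solver's matrix positive definite when the Gram matrix is rank-deficient).
The refinement solves the stationarity system on the identified free set,
moves box violators to their bounds and releases bound points with
wrong-signed multipliers one at a time, and falls back to the solver's
answer if the system degenerates. In the test suite this pipeline agrees
with an exhaustive KKT enumeration oracle and with an independent libsvm fit
to near machine precision. Iterative SMO solvers were measured to be three
orders of magnitude slower on these Gram matrices (diagonal ≈ 1e5) and to
return visibly non-converged weights, which motivated the exact solver.

The bias is computed from the optimal weights as the exact minimizer of the
piecewise-linear hinge objective in the bias alone, taking the midpoint of
the minimizing interval. For separable data this is the canonical
max-margin bias (equidistant from the closest points of both classes), and
the computation does not depend on classifying alphas as bound or free,
which is numerically fragile.

Cases are coded so that the pathological class falls on the *negative* side
of the hyperplane: a negative signed geometric distance
`d = (w·x + b)/‖w‖` means "classified amyloid-positive", and the magnitude
of `d` measures the strength of evidence. A case exactly on the hyperplane
(`d = 0`) is assigned to the normal class; this tie rule is a documented
package convention.

## Quantification: SUVR and Centiloids

Voxelwise SUVR is the raw volume divided by the mean of the cerebellar
grey-matter mask; the pons is used as reference for the staging inputs. The
composite VOI is the union of the five cortical regions (frontal, parietal,
anterior cingulate, posterior cingulate, lateral temporal), and its mean
SUVR converts to Centiloids through one of two published affine
calibrations: `CL = 127.6 · SUVR_comp − 149` (MRI-assisted processing) and
`CL = 210.49 · SUVR_comp − 250.13` (PET-only). In the phantom there is a
single processing path, so the two arms differ only by which printed formula
is applied; both are carried through the transfer analysis to mirror the
dual-processing design. `calibrate_centiloid()` re-derives such a
calibration by ordinary least squares from (SUVR, reference CL) pairs. The
grey-matter-map intersection of the MRI-assisted procedure is represented by
the atlas masks directly, since the phantom has no segmentation.

## PET amyloid staging

Two threshold-based staging schemes are implemented over pons-referenced
cortical and caudate SUVRs. The four-level phase-estimate scheme uses the
printed disjunctive rules (estimate 1: cortex ≥ 0.5 and/or caudate ≥ 0.6;
estimate 2: cortex ≥ 0.6 and/or caudate ≥ 0.7; estimate 3: cortex ≥ 0.6
and/or caudate ≥ 1.0), taking the highest satisfied rule. Because the
cortical threshold 0.6 appears in both the estimate-2 and estimate-3 rules,
the literal reading lets cortex alone reach estimate 3 and estimate 2 is
rarely observed; the `thal_strict_caudate` switch instead requires caudate
≥ 1.0 for estimate 3. Both readings are available so the ambiguity is
surfaced rather than silently resolved; the literal reading is the default.
The three-level scheme maps (cortical, striatal) positivity to stages
0/1/2 and rejects the undefined striatal-only cell.

Both schemes are defined on visual reads in their original form. The
package never emulates a reader; the pipeline derives read *surrogates* by
thresholding the semi-quantitative SUVRs (cortical positivity at 0.6,
striatal at 0.7 by default, both configurable) and flags them as surrogates
in the output. The surrogate counts striatal positivity only in
cortical-positive cases so that noise cannot produce the undefined cell.

## The inferential toolkit

* `roc_youden()` — empirical ROC with thresholds midway between consecutive
  distinct scores, trapezoidal AUC (ties count one half, so AUC equals the
  scaled Mann–Whitney count), and the cut-off maximizing Youden's J;
  among tied maximizers the largest (most conservative for positivity)
  threshold is reported and all maximizers are listed.
* `compare_overlapping_correlations()` — Dunn & Clark's (1969) z for two
  overlapping correlations on dependent groups, via Fisher transforms; the
  degenerate case of exactly equal correlations returns `z = 0, p = 1`
  directly, where the variance expression would otherwise be 0/0.
* `welch_anova()`, `pairwise_welch_bonferroni()` — heteroscedastic group
  comparisons (base R's `oneway.test`/`t.test` behind the module surface),
  with `p_adj = min(1, m·p)`.
* `kruskal_wallis()`, `mann_whitney()` — tie-corrected rank tests. The
  Mann–Whitney p-value is computed by exhaustive enumeration of group
  assignments when both groups have at most 8 observations (this handles
  ties exactly, which the classical exact distribution does not), and by
  the tie-corrected normal approximation with continuity correction above
  that bound. The fully degenerate Kruskal–Wallis case (all values equal)
  returns `H = 0, p = 1` rather than an error.

## The phantom: what it emulates and what it does not

The phantom atlas is a deterministic label volume (default 40×48×40 voxels
at 4 mm, ≈25k brain voxels) with eleven regions: the five composite-VOI
cortical regions, precuneus, caudate, cerebellar grey matter, pons, white
matter and background, placed as axis-aligned boxes with the reference
regions disjoint from the cortical compartment. The default grid is large
enough for a meaningful voxel classifier yet small enough that the full
50-repeat LOO ensemble suite runs in minutes on one CPU.

The signal model encodes the hierarchical spreading of amyloid: cortical
regions begin accumulating signal at phase 1 (0.22 SUVR per phase step by
default), the caudate at phase 3 (0.45 per step, so striatal signal
discriminates the advanced phases, mirroring the staging schemes), and the
reference regions never accumulate specific signal. A neuritic coupling
term adds 0.15 SUVR per unit of maximal regional CERAD density. White
matter carries high nonspecific retention (baseline 1.6) and the pons a
high baseline (2.8), chosen so that pons-referenced cortical SUVR sits just
below the staging thresholds at zero burden and crosses them as burden
grows. Voxel noise (SD 0.25) is added *before* 5-mm FWHM Gaussian
smoothing, mimicking spatially correlated PET noise; smoothing uses mirror
reflection at the volume boundary, which avoids edge darkening on small
phantoms and makes the convolution exactly testable.

Two subject-level random effects provide biological heterogeneity: a
log-normal amplitude multiplier on the specific signal (SD 0.35 on the log
scale) and an additive per-region shift (SD 0.08 SUVR) in signal regions.
These are what keep the synthetic cohorts *near*-separable: with voxel
noise alone, averaging over thousands of voxels makes classes perfectly
separable and every ensemble trivially reaches 100%. With the defaults the
original classifiers reach mean accuracies in the high 80s to mid 90s with
nonzero spread — the intended regime of clearly-better-than-chance but
imperfect classification.

The end-of-life-like composition reproduces the published cross-table of
Bielschowsky status by amyloid phase — 29 negative/72 positive, 22 low/79
high, including 7 discordant BSS-negative cases at phases 3–5 — exactly,
cell by cell. CERAD densities are drawn conditionally on phase and class
(class membership is enforced, the phase shifts the distribution upward).
The asymptomatic-like cohort (180 subjects) draws a *continuous* amyloid
burden from a right-skewed mixture — 70% from an exponential low-burden
component (mean 0.7 on the phase scale) and 30% from a Gaussian elevated
component (mean 3.3, SD 0.9), clipped to [0, 5] — so a low-burden majority,
an elevated minority and genuine intermediates all exist. The published
description of the real asymptomatic cohort does not constrain its burden
distribution, so these mixture parameters are package defaults, not claims
about any real cohort.

All randomness flows from one master seed: subject `i` uses child seed
`(seed + 7919·i) mod (2³¹−1)`, ensemble repeat `r` uses
`(seed + 104729·r) mod (2³¹−1)`, and the four ensembles receive distinct
master-seed offsets. Two runs with the same configuration produce
byte-identical outputs, which the test suite verifies on disk.

What the phantom does *not* emulate: brain geometry, spatial normalization
and registration, scanner physics, partial-volume effects, atrophy, and
reader behaviour. Passing tests therefore demonstrate the correctness and
stability of the *procedure* — balanced resampling, exact SVM optimization,
scoring, quantification, staging, statistics — under a controlled data
model, not the real-data operating characteristics of the method; the
published performance numbers cannot be reproduced without the original
cohorts.

## Numerical choices and degenerate inputs

* Gaussian kernels are sampled at voxel centres, truncated at 6σ and
  renormalized to unit mass, so constants are preserved exactly and
  repeated smoothing composes like a single wider kernel to ~1e-9 once the
  kernel sigma exceeds ~1.3 voxels (below that, point sampling dominates).
* `fwhm = 0` smoothing is the identity; empty masks, single-class labels,
  zero-variance groups, perfect correlations and out-of-range fractions
  raise errors rather than propagating NaN.
* Minority classes smaller than 3 cases make LOO degenerate and are
  rejected.
* Exact cancellation when averaging classifiers (zero mean weight vector)
  violates the positive-norm invariant and is rejected.
* The top-weight tie-break (ascending voxel index) and the `round()` voxel
  count are package conventions, stated so tests can be exact.

## Problem sizes used by the tests

The structural test suite runs on a reduced 20×24×20 grid with 5 ensemble
repeats and a 40-subject transfer cohort; the end-to-end suite runs the
full default configuration (40×48×40, 50 repeats, 101 + 180 subjects)
once, in roughly half a minute, and checks the qualitative pattern the
default generator is designed to produce: all four classifiers above 80%
mean accuracy, median distance to the hyperplane non-increasing across
amyloid phases, negative distance–Centiloid correlations with the
phase-trained classifiers correlating more strongly than the BSS-trained
ones, and the select-phase classifier yielding the lowest Centiloid
cut-off.

## Limitations

The phantom's regional boxes are not anatomy, its signal model is linear in
phase, and its read surrogates are thresholds, so numbers computed on it
live on the phantom's own scale (e.g. Centiloid values track the printed
conversion formulas applied to phantom SUVRs, not the GAAIN calibration
pipeline). The staging thresholds are tracer-specific printed values and
are not recalibrated to the phantom. The Grothe-style four-stage scheme and
nonlinear kernels are out of scope.
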