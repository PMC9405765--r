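---
title: "Methods: multimodal five-year recurrence modelling on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal five-year recurrence modelling on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmrecur` re-implements, end to end, a multimodal modelling strategy for
predicting five-year breast-cancer recurrence before neoadjuvant
chemotherapy: a deep imaging branch over multiparametric MRI, a classical
tabular branch over clinical history, censoring-aware cross-validation
with side-model pseudo-labels, Platt-calibrated seed-variation
ensembling, and an evaluation stack built around high-sensitivity
operating points and prognostic subgroups. Because cohorts of this kind
are private hospital data, the package's subject matter is the *method*,
exercised on synthetic data whose generating truth is known. This
vignette records the models, the parameters that matter, and the design
decisions taken where the method description left choices open.

## What the synthetic data emulate — and what they do not

`generate_cohort()` draws a clinical table shaped like an NAC population:
age and BMI with realistic marginals; cancer subtype (TNBC / Luminal A /
Luminal B / HER2+) driving HER2 and progesterone status; grade driving
Ki67 and mitotic index; a clinician's tumor-size estimate; 5–15%
missingness per feature. The five-year outcome is Bernoulli under a
logistic model on standardized scales with default coefficients
log-volume +1.2, BMI −0.6, age −0.6, HER2 −0.9. Directions follow the
prognostic literature for this population: tumor burden is the dominant
risk factor; younger age and lower BMI carry higher risk in NAC cohorts;
HER2-positive disease has better outcomes in the era of anti-HER2
therapy. Magnitudes were fixed once at values giving a Bayes-optimal AUC
in the low 0.8s — the regime in which recurrence prediction is hard but
learnable, so parameter-recovery experiments have headroom in both
directions. The intercept is solved numerically so the expected positive
rate hits its 16% target; censoring is drawn independently at 40%.

`generate_phantom()` renders an axial mpMRI study: two ellipsoidal
breasts (a fat/gland voxel mixture) on a voxel grid, zero or more
ellipsoidal lesions, and four volume types (DCE subtraction, ADC, Dixon
water-only, fat-only) with class-mean intensities plus additive Gaussian
noise. Lesions are bright on subtraction, water-only *and* ADC — the
selection rule the segmentation stage implements expects high lesion ADC,
and the phantom follows that rule as stated rather than typical diffusion
physics, where cellular tumors often show *low* ADC. Class means are
required to be at least 3 noise SD apart, so clustering is solvable by
construction. In the pipeline, each imaging patient's lesion volume
realizes the latent volume that drives their outcome risk, with mild
random anisotropy and center jitter; the clinical table's tumor-size
proxy is a noisy correlate of the same latent quantity, so both branches
carry overlapping but non-identical signal — the regime in which
ensembling them is worthwhile.

Not emulated: MR physics (coil bias fields, DCE pharmacokinetics, partial
volume beyond voxelization), registration error between series, scanner
heterogeneity, informative censoring, and the correlation structure of
real clinical records beyond the dependencies listed above. Passing tests
therefore demonstrate that the *pipeline machinery* recovers known
structure under controlled conditions — not clinical performance.

## Segmentation

Fuzzy c-means (`fcm()`) is the classical alternating scheme minimizing
$\sum_i \sum_j u_{ij}^m \lVert x_i - c_j\rVert^2$ with fuzziness $m = 2$,
tolerance $10^{-4}$ on the maximum center shift, and a 300-iteration cap.
Centers are initialized deterministically at quantiles of the projection
onto the dominant principal direction; memberships renormalize each step
and the objective trace is non-increasing (both asserted in tests).

Phase 1 clusters every voxel's (water, fat) pair with $k = 3$
(background / fat-dominant / water-dominant); any cluster whose total
center intensity exceeds 1.5× the background cluster's counts as breast
tissue — on an all-background volume nothing passes and empty masks are
returned with a warning. The tumor-side mask restricts the bilateral mask
to the annotated half-grid. Phase 2 reclusters voxels inside the
tumor-side mask on (water, ADC) — water alone when ADC is unavailable —
and selects as lesion the cluster(s) with the largest *Dice* overlap
against the high-intensity area, defined as the intersection of the top
5% of in-mask intensities on water and on ADC.

Three choices here were forced by experiment rather than taste. First,
scoring clusters by the *fraction of their voxels* inside the
high-intensity area silently rejects any lesion larger than the top-5%
area itself — a 60 mm NAC tumor can be 12% of the breast — so the
symmetric Dice overlap is used, with acceptance threshold 0.15. Second,
single-start FCM reliably falls into a local minimum that merges a large
lesion with parenchyma; phase 2 therefore restarts from two
initializations (quantiles spanning the full range, and an upper-quantile
spread) and keeps the lower final objective. Third, initialization
quantiles extend to the extremes (0 and 1) so that a small bright lesion
— a fraction of a percent of the voxels — still attracts a center.
Defuzzification is argmax membership with ties to the lower cluster
index; all region reasoning uses 26-connectivity.

## Volumetric features

From the largest lesion region (`count_regions()`, components via the
voxel adjacency graph): volume = voxel count × voxel volume; surface area
from a marching-tetrahedra isosurface at level 0.5 over the indicator
smoothed with a σ = 1 voxel Gaussian (the smoothing moves interpolated
vertices onto the true interface; the raw binary staircase overestimates
a sphere's area by ~28%, the smoothed surface is within ~1% at radius
10 mm — if smoothing would erase a tiny object entirely, the raw
indicator is measured instead); intensity ratio = mean lesion intensity
over mean non-lesion breast intensity on the water-suppression Dixon
contrast, read as the fat-visible volume (`intensity_volume = "fat"`,
configurable, since the segmentation uses the water-*only* volume and the
feature names the water-*suppression* one — two different Dixon
contrasts); spread = Σ over axes of (inclusive index extent + 1) ×
spacing. An empty lesion zeroes the geometric features and sets a missing
flag that travels into the Dixon vector. The Dixon vector appends
configurable clinical metadata (default: age, BMI, tumor size, grade);
imputation of any missing entry uses training-fold means only, at
training time.

## Slice preparation

`extract_slices()` takes the annotated significant slice ±3 in
acquisition order; indices beyond the volume edge replicate the terminal
slice (preserving the 7-slice contract without zero-padding artifacts).
`standardize_slices()` splits at the mid-sagittal column and keeps the
tumor side, flips right-sided studies so every output faces the same
direction, trims margin rows/columns whose stack maximum falls below 5%
of the stack maximum, resizes bilinearly to 512 × 256 (reduced profiles
keep the 2:1 aspect), and min-max normalizes the stack to [0, 1].
Orientation comes from the manifest annotation, not from the image.
Standardization is *defined* on raw bilateral slices; on an
already-standardized stack it is the identity (the vertical split has no
meaning on a half image), which is how the idempotence property is
realized. `undersample_overlap()` keeps every k-th slice with
k = ⌈thickness/spacing⌉ — a committed reading of "under-sample where
slices overlap".

## The imaging network

The architecture is fixed: a shared-weight 2D trunk (stem 3×3 conv, then
7 residual blocks with widths 32, 64, 64, 128, 128, 256, 256 and stride-2
downsampling at each width increase, in the reduced-filter ResNet18
pattern) applied identically to each of the 7 slices; feature maps
stacked along a depth axis; one 3D convolution with a depth-3 kernel over
the slice axis (pointwise in plane) and 32 output channels; global
average pooling to exactly 32 subtraction features; a (16, 16, 16, 32,
32) dense Dixon head; fusion layers (64, 32, 1) with a sigmoid.
`network_architecture()` exposes the stage table for introspection, and
tests pin it.

Two design decisions depart from a conventional end-to-end training
setup. The trunk is used as a **frozen random-feature encoder**: it is
initialized once from the spec seed (He-scaled) and never updated, with
per-sample instance normalization in place of batch statistics so the
encoder is deterministic. Random convolutional features are a
long-standing, well-characterized encoder family, and the phantom's
imaging signal — lesion brightness and extent — is low-frequency contrast
that such features capture; what must adapt to the outcome is the
aggregation and fusion, which are exactly the trainable stages (3D
convolution, Dixon head, fusion head). This also makes desk-scale
training cheap enough to run inside a test suite on one CPU. Second,
because global average pooling after the depth-3 convolution is *linear
in the kernel*, the entire subtraction branch collapses onto a 768-value
sufficient statistic per patient (per-tap, per-channel means of the
depth-shifted trunk maps); training operates on that statistic, and a
test asserts bit-level agreement with the explicit
trunk → conv3d → pooling path.

Training: class-weighted binary cross-entropy, Adam at learning rate
3e-3, minibatch 32, at most 200 epochs with early stopping (patience 30)
on the validation-fold loss. With only the small dense stages trainable,
this longer, larger-rate schedule is what actually reaches the input
signal's ceiling — on a cohort whose outcome is driven by lesion volume
alone, out-of-fold AUC matches the AUC of the measured volume feature
itself (~0.83); a short low-rate schedule stalls near 0.64. Gradients are
hand-derived and verified against numerical differentiation in tests.

## Clinical branch, censoring, ensembling, evaluation

The tabular preprocessing fits mean imputation (raw scale) then min-max
scaling on training folds only; held-out values outside the training
range clamp to [0, 1]; constant columns scale to zero. Class weighting is
n/(2n_c) per sample and n_neg/n_pos as the boosting positive scale.
Candidate families: random forest (500 trees, √p features, case
weights), ridge logistic regression (penalty matched to an L2 C = 1
formulation), gradient boosting (depth 4, 300 rounds, rate 0.05);
selection by mean cross-validation AUC. Attributions: exact TreeSHAP for
boosted models (log-odds scale); otherwise a permutation-sampling Shapley
estimator whose telescoping construction is exactly efficient per
permutation — attributions always sum to the prediction minus the mean
background prediction. The explanation protocol mirrors the study design:
one model of the selected family trained on the whole cohort
(pseudo-labels included), with a complete-case re-run available
(`complete_cases = TRUE`).

Censored patients never appear in any validation or evaluation set; they
stay in training folds under pseudo-labels from a random-forest side
model trained on all uncensored patients (threshold 0.5). The default
shares one side model across folds — its optimism can only reach training
data — and a stricter per-fold mode (`per_fold = TRUE`) is provided.
Folds are stratified jointly by outcome and imaging availability with a
rotation that continues across strata, so positive counts balance to ±1
both in the full cohort and in the imaging subset, and a patient with
imaging keeps one fold in both cohort views. Censored patients are spread
by side-model score so training folds stay comparable.

Each branch is trained as three seed variations; each variation is Platt
calibrated — σ(a·s + b) fitted by maximum likelihood with Platt's
prior-corrected targets — on its own *out-of-fold* scores (never training
scores; holdout scoring reuses these calibrators, so no holdout label can
influence anything). The ensemble score is the mean of a patient's
available calibrated scores: six for imaging patients, three otherwise.
Calibration is strictly monotone, so each model's AUC is unchanged — an
audited invariant.

Evaluation: rank-statistic AUC (ties at ½) with class-stratified
percentile-bootstrap CIs (2000 resamples by default; the pipeline's
summary intervals use 1000); operating points at targets 0.87/0.90/0.93
choosing the largest threshold whose sensitivity reaches the target;
McNemar on discordant counts, exact binomial below b + c = 25 and
continuity-corrected χ² above; Bonferroni at α = 0.05 over 12 tests
(threshold 0.0042). The subgroup scan enumerates all 432 cells of age
(≤50, 50–60, ≥60, missing — with 50 in the first band and 60 in the
last), subtype (luminal, TNBC, HER2+, missing), histological type (NST,
other, missing), grade (I–II, III, missing) and Ki67 (≤15%, >15%,
missing); a cell is analyzed when it holds ≥10 patients with both
outcomes present, and analyzed cells are reported AUC-descending with
bootstrap CIs.

## Numerical choices and degenerate inputs

Quantile type 7 everywhere; FCM distance floors at 1e-300 with exact-hit
handling; defuzzification ties to the lower cluster index; region-size
ties to the region containing the lowest linear voxel index; constant
preprocessing columns to zero; empty lesion masks propagate a missing
flag rather than NaNs; single-class label vectors are errors in every
fitting routine; all seeds derive from one master seed through a labelled
31-bit stream.

## Problem sizes

The package's desk-scale defaults, used by the test suite and the
acceptance script: cohorts of 800 patients with a 200-patient imaging
subset; phantom grids 48 × 24 × 16 voxels at 4 mm spacing (default
standalone phantoms 64 × 32 × 20 at 3 mm); slice stacks at 32 × 16; 1000
bootstrap resamples in pipeline summaries. The production 512 × 256 slice
geometry and full architecture widths are always in force; only spatial
sampling is reduced.

## Known limitations

The frozen-trunk design means the imaging branch cannot learn spatial
patterns beyond what random features encode; on real data one would
unfreeze the trunk. Phantom intensity classes are unimodal Gaussians, so
segmentation difficulty is controlled entirely by the noise/contrast
ratio. The water-only no-ADC lesion rule is weaker at rejecting
lesion-free breasts (a single-contrast high-intensity area always
exists). Pseudo-labels at a 0.5 threshold label almost all censored
patients negative at a 16% base rate — faithful to the scheme, but a
known attenuation of training signal. Subgroup AUCs on cells near the
10-patient floor carry very wide bootstrap intervals.
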