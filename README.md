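# mmrecur

Multimodal modelling of five-year breast-cancer recurrence for patients
receiving neoadjuvant chemotherapy (NAC), as a tested, fully synthetic and
reproducible R pipeline.

## The problem

When NAC is being considered for locally advanced breast cancer, the
likelihood of recurrence within five years of diagnosis is a central
clinical question, yet standard practice uses only a handful of prognostic
biomarkers (age, hormone receptor status, HER2, tumor size, grade, Ki67).
Two further sources of pre-treatment information exist in routine records:
the clinical history table, and the multiparametric MRI study (DCE
subtraction, ADC, and Dixon water-only/fat-only volumes) acquired before
treatment starts. Real cohorts of this kind are private; `mmrecur`
therefore ships a first-class synthetic-data module — mpMRI phantoms with
known lesion geometry and clinical cohorts with a known logistic risk
structure — so that every stage of the method can be exercised, tested and
audited without any external data.

## The method

Two branches, combined by calibrated score averaging:

* **Imaging branch.** The annotated significant slice and its six
  neighbours are cropped to the tumor side, trimmed to the breast, resized
  to 512 × 256 and fed to a shared-weight 2D residual trunk (7 blocks,
  filter widths 32, 64, 64, 128, 128, 256, 256); per-slice feature maps are
  stacked, passed through a depth-3 3D convolution and global average
  pooling into 32 subtraction features. In parallel, a two-phase fuzzy
  c-means segmentation (phase 1: breast tissue from Dixon water/fat;
  phase 2: lesion clusters selected by their overlap with high-intensity
  areas on ADC and water-only volumes) yields masks from which five
  volumetric features are computed — tumor volume (mm³), surface area
  (mm²), number of separate regions, lesion-to-breast intensity ratio on
  the water-suppression Dixon contrast, and spread (the sum of maximal x,
  y, z extents, mm). These, plus clinical metadata, pass through a dense
  head (16, 16, 16, 32, 32) and are fused with the subtraction features
  through layers (64, 32, 1) into the mpMRI score.
* **Clinical branch.** Min-max scaling and mean imputation (training folds
  only), class-imbalance weighting, and a model family selected by
  cross-validation AUC among random forest, ridge logistic regression and
  gradient boosting; attributions via Shapley values (exact TreeSHAP for
  boosted trees, an exactly-efficient permutation-sampling estimator
  otherwise).
* **Censoring and validation.** Patients diagnosed less than five years
  before data collection have no observable outcome. A random-forest side
  model trained on uncensored patients pseudo-labels them for training
  folds only; stratified 5-fold cross-validation keeps every evaluation
  set purely uncensored, and a patient with imaging keeps the same fold in
  both cohort views.
* **Ensemble and evaluation.** Three seed variations per branch are
  Platt-calibrated on their out-of-fold scores and averaged per patient
  ("mean of all available scores"). Evaluation: AUC with stratified
  percentile-bootstrap 95% CI, metrics at sensitivity operating points
  0.87/0.90/0.93, McNemar tests with Bonferroni correction (α = 0.05, 12
  tests, threshold 0.0042), and a combinatorial prognostic subgroup scan
  over 432 = 4·4·3·3·3 cells of age, cancer subtype, histological type,
  grade and Ki67.

## Worked example

```r
library(mmrecur)
res <- run_recurrence_pipeline(seed = 1)
res
#> Multimodal recurrence pipeline (seed 1 )
#>   cohort: 800 patients (200 imaging), 502 uncensored
#>   selected clinical family: rf
#>   AUC ensemble (clinical cohort): 0.816 [0.746, 0.877]
#>   AUC ensemble (imaging cohort):  0.814 [0.718, 0.904]
#>   AUC clinical (imaging cohort):  0.795 [0.681, 0.894]
#>   AUC mpMRI    (imaging cohort):  0.777 [0.659, 0.873]
#>   audits: 10/10 passed
```

```r
head(res$attribution$ranking, 3)
#>          feature   mean_abs
#> 10 tumor_size_mm 0.16490621
#> 2            bmi 0.08811757
#> 1            age 0.05367491
```

The synthetic cohort draws a five-year recurrence outcome (16% positive,
40% censored) from a logistic model in which larger lesion volume raises
risk while higher BMI, older age and HER2-positive status lower it. The
printed AUCs say that, out of fold, the ensemble recovers that risk
structure better than either branch alone, on evaluation sets that never
contain a censored patient. `res$attribution$ranking` lists the clinical
features by mean absolute Shapley value (the generator's true drivers —
tumor size, BMI, age — rank at the top), `res$operating_points` holds the
fixed-sensitivity metrics grid, `res$mcnemar` the paired comparisons, and
`run_recurrence_pipeline(seed = 1, run_subgroups = TRUE)` adds the
432-cell subgroup table.

Lower-level entry points (`generate_phantom()`, `segment_study()`,
`extract_volumetric_features()`, `prepare_slice_stack()`,
`build_subtraction_net()`, `train_select()`, `train_mpmri()`,
`fit_platt()`, `subgroup_scan()`, ...) expose each stage separately; the
methods vignette (`vignettes/mmrecur-methods.Rmd`) documents the models,
parameters and design choices.

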