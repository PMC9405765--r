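test_that("phantom with no lesions has an all-zero truth mask", {
  ph <- generate_phantom(phantom_spec(lesions = list(), seed = 5))
  expect_equal(sum(ph$truth$lesion_mask), 0)
  expect_equal(ph$truth$lesion_count, 0L)
  expect_equal(ph$truth$analytic_volume, 0)
})

test_that("spherical lesion volume matches the analytic value within a voxel shell", {
  r <- 6
  sp <- phantom_spec(shape = c(40L, 40L, 40L), spacing = c(1, 1, 1),
                     breasts = list(left = list(center = c(20, 20, 20), semiaxes = c(15, 15, 15)),
                                    right = list(center = c(120, 20, 20), semiaxes = c(15, 15, 15))),
                     lesions = list(list(center = c(20, 20, 20), semiaxes = c(r, r, r),
                                         side = "left")),
                     seed = 2)
  ph <- generate_phantom(sp)
  analytic <- 4 / 3 * pi * r^3
  expect_equal(ph$truth$analytic_volume, analytic, tolerance = 1e-10)
  # voxel-count volume within one voxel-shell surface band of the analytic value
  vox_vol <- sum(ph$truth$lesion_mask) * 1
  shell <- 4 * pi * r^2 * 1  # surface area x max spacing
  expect_lt(abs(vox_vol - analytic), shell)
  # independent voxel-count oracle over the sphere indicator
  cx <- (1:40) - 0.5
  oracle <- sum(outer(outer((cx - 20)^2, (cx - 20)^2, "+"), (cx - 20)^2, "+") <= r^2)
  expect_equal(vox_vol, oracle)
})

test_that("phantom generation is bit-identical for the same seed", {
  sp <- phantom_spec(seed = 9)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$study$volumes, b$study$volumes)
  expect_identical(a$truth$lesion_mask, b$truth$lesion_mask)
})

test_that("volume conservation holds across lesion geometries", {
  for (sd in 1:5) {
    semi <- c(10 + sd, 9 + sd / 2, 8 + sd / 3)
    sp <- phantom_spec(lesions = list(list(
      center = phantom_spec()$breasts$left$center, semiaxes = semi, side = "left")),
      seed = sd)
    ph <- generate_phantom(sp)
    vox <- sum(ph$truth$lesion_mask) * prod(sp$spacing)
    # ellipsoid surface area (Thomsen approximation) x max spacing band
    p <- 1.6075
    sa <- 4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
                       semi[2]^p * semi[3]^p) / 3)^(1 / p)
    expect_lt(abs(vox - ph$truth$analytic_volume), sa * max(sp$spacing))
  }
})

test_that("generated tissue classes are separable by at least 3 noise SD", {
  sp <- phantom_spec(seed = 3)
  ph <- generate_phantom(sp)
  tis <- ph$truth$tissue
  for (v in colnames(sp$intensity_means)) {
    vol <- if (v == "subtraction") ph$study$volumes$subtraction[[1]] else
      ph$study$volumes[[v]]
    mns <- tapply(as.vector(vol), as.vector(tis), mean)
    d <- abs(outer(mns, mns, "-"))
    # empirical class means estimate the >= 3 SD generating separation
    expect_gte(min(d[upper.tri(d)]), 2.5 * sp$noise_sd[[v]])
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(spacing = c(1, -1, 1)), "spacing")
  expect_error(phantom_spec(lesions = list(list(center = c(500, 500, 500),
                                                semiaxes = c(5, 5, 5), side = "left"))),
               "inside")
})

test_that("cohort positive rate matches target within binomial error", {
  co <- generate_cohort(cohort_spec(n = 10000L, positive_rate = 0.5,
                                    censoring_rate = 0,
                                    risk_coefs = c(bmi = 0, age = 0, her2 = 0,
                                                   log_volume = 0),
                                    missingness = list(), seed = 21))
  expect_gte(mean(co$true_outcome), 0.47)
  expect_lte(mean(co$true_outcome), 0.53)
})

test_that("zero missingness yields a complete table", {
  co <- generate_cohort(cohort_spec(n = 500L, missingness = list(), seed = 4))
  expect_false(anyNA(co[, clinical_feature_names()]))
})

test_that("a strongly negative BMI coefficient lowers BMI among positives", {
  co <- generate_cohort(cohort_spec(n = 5000L, censoring_rate = 0,
                                    risk_coefs = c(bmi = -2, age = 0, her2 = 0,
                                                   log_volume = 0),
                                    missingness = list(), seed = 8))
  expect_lt(mean(co$bmi[co$true_outcome == 1]), mean(co$bmi[co$true_outcome == 0]))
})

test_that("cohort generation is deterministic and validates its spec", {
  a <- generate_cohort(cohort_spec(n = 100L, seed = 5))
  b <- generate_cohort(cohort_spec(n = 100L, seed = 5))
  expect_identical(a, b)
  expect_error(cohort_spec(n = 10L), "at least 20")
  expect_error(cohort_spec(positive_rate = 1.4), "\\[0, 1\\]")
  # too few positives for stratified 5-fold
  expect_error(generate_cohort(cohort_spec(n = 30L, positive_rate = 0.01,
                                           seed = 1)), "too few")
})

test_that("censoring is independent of features by default", {
  co <- generate_cohort(cohort_spec(n = 6000L, missingness = list(), seed = 13))
  expect_lt(abs(cor(co$censored, co$latent_log_volume)), 0.04)
  expect_lt(abs(cor(co$censored, co$bmi)), 0.04)
})

test_that("NIfTI round trip preserves volumes, spacing and annotations", {
  ph <- generate_phantom(phantom_spec(shape = c(16L, 12L, 8L), spacing = c(2, 3, 4),
                                      lesions = list(), seed = 2))
  dir <- withr::local_tempdir()
  mpath <- write_mri_study(ph$study, dir, truth = ph$truth)
  back <- read_mri_study(mpath)
  expect_equal(back$volumes$water, ph$study$volumes$water, tolerance = 1e-6)
  expect_equal(back$spacing, c(2, 3, 4))
  expect_equal(back$annotations$significant_slice,
               ph$study$annotations$significant_slice)
  expect_equal(attr(back, "truth_masks")$breast_mask_left, ph$truth$breast_mask_left)
  # cohort CSV round trip
  co <- generate_cohort(cohort_spec(n = 40L, seed = 3))
  p <- file.path(dir, "cohort.csv")
  write_cohort_csv(co, p)
  expect_equal(read_cohort_csv(p)$patient_id, co$patient_id)
})
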