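test_that("region counting matches a flood-fill oracle on random masks", {
  for (sd in 1:4) {
    set.seed(sd)
    m <- array(runif(20^3) < 0.18, c(20, 20, 20))
    lab <- label_components(m)
    oracle <- floodfill_label(m)
    expect_equal(max(lab), max(oracle))
    # same partition: every component maps one-to-one
    expect_equal(length(unique(paste(lab[m], oracle[m]))), max(lab))
  }
})

test_that("two disjoint spheres count as two regions, larger one returned", {
  m <- array(FALSE, c(30, 20, 20))
  cx <- function(c0, r) {
    idx <- which(array(TRUE, dim(m)))
    co <- arrayInd(idx, dim(m))
    keep <- (co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2 + (co[, 3] - c0[3])^2 <= r^2
    idx[keep]
  }
  m[cx(c(8, 10, 10), 5)] <- TRUE
  m[cx(c(22, 10, 10), 3)] <- TRUE
  cr <- count_regions(m)
  expect_equal(cr$n_regions, 2L)
  expect_true(all(which(cr$largest) %in% cx(c(8, 10, 10), 5)))
  expect_equal(count_regions(array(FALSE, c(5, 5, 5)))$n_regions, 0L)
})

test_that("digital sphere features match the analytic oracle", {
  m <- digital_sphere(10, 1)
  intens <- array(1, dim(m)); breast <- array(TRUE, dim(m))
  vf <- compute_features(m, 1L, intens, breast, c(1, 1, 1))
  expect_lt(abs(vf$tumor_volume - 4188.79) / 4188.79, 0.05)
  expect_lt(abs(vf$surface_area - 1256.64) / 1256.64, 0.10)
  expect_equal(vf$spread, 3 * (2 * 10 + 1), tolerance = 0.1)
})

test_that("single-voxel lesion has volume 1 mm3 and spread 3 mm", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  vf <- compute_features(m, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(1, 1, 1))
  expect_equal(vf$tumor_volume, 1)
  expect_equal(vf$spread, 3)
  expect_equal(vf$n_regions, 1L)
})

test_that("intensity ratio is exact on a constructed two-level volume", {
  m <- digital_sphere(4, 1)
  breast <- array(TRUE, dim(m))
  intens <- array(50, dim(m)); intens[m] <- 100
  vf <- compute_features(m, 1L, intens, breast, c(1, 1, 1))
  expect_equal(vf$intensity_ratio, 2, tolerance = 1e-6)
})

test_that("features obey the spacing scaling law", {
  set.seed(11)
  m <- digital_sphere(6, 1)
  a <- compute_features(m, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(1, 1, 1))
  b <- compute_features(m, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(2, 2, 2))
  expect_equal(b$tumor_volume / a$tumor_volume, 8, tolerance = 1e-9)
  expect_equal(b$surface_area / a$surface_area, 4, tolerance = 1e-9)
  expect_equal(b$spread / a$spread, 2, tolerance = 1e-9)
})

test_that("features are translation invariant", {
  m <- array(FALSE, c(30, 30, 30))
  m[5:9, 6:11, 7:13] <- TRUE
  m2 <- array(FALSE, c(30, 30, 30))
  m2[15:19, 16:21, 17:23] <- TRUE
  f1 <- compute_features(m, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(1, 1, 1))
  f2 <- compute_features(m2, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(1, 1, 1))
  for (f in c("tumor_volume", "surface_area", "spread")) {
    expect_equal(f1[[f]], f2[[f]], tolerance = 1e-9)
  }
})

test_that("sphere volume error decreases monotonically with radius", {
  errs <- vapply(c(4, 8, 16), function(r) {
    m <- digital_sphere(r, 1)
    vf <- compute_features(m, 1L, array(1, dim(m)), array(TRUE, dim(m)), c(1, 1, 1))
    abs(vf$tumor_volume - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("empty lesions yield zeroed features with the missing flag", {
  vf <- compute_features(array(FALSE, c(5, 5, 5)), 0L, array(1, c(5, 5, 5)),
                         array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  expect_true(vf$lesion_missing)
  expect_equal(vf$tumor_volume, 0)
  expect_true(is.na(vf$intensity_ratio))
  v <- assemble_dixon_vector(vf, list(age = 50, bmi = 25, tumor_size_mm = 30,
                                      tumor_grade = 2))
  expect_equal(unname(v["tumor_volume"]), 0)
  expect_equal(unname(v["lesion_missing"]), 1)
})

test_that("dixon vectors have constant length and reject unknown metadata", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  seg <- segment_study(ph$study, seed = 12)
  vf <- extract_volumetric_features(seg$masks, ph$study)
  row <- list(age = 41, bmi = 23, tumor_size_mm = 28, tumor_grade = 3)
  v <- assemble_dixon_vector(vf, row)
  expect_length(v, 10L)
  expect_error(assemble_dixon_vector(vf, row, metadata_fields = "shoe_size"),
               "unknown clinical metadata")
})

test_that("imputation fills held-out missing entries with training-fold means", {
  set.seed(13)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[3, 2] <- NA; x[18, 1] <- NA
  train <- 1:10
  imp <- impute_by_train_means(x, train)
  expect_equal(unname(imp$x[3, 2]), mean(x[train, 2], na.rm = TRUE))
  expect_equal(unname(imp$x[18, 1]), mean(x[train, 1], na.rm = TRUE))
  x[, 3] <- NA
  expect_error(impute_by_train_means(x, train), "entirely missing")
})
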