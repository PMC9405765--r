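test_that("min-max preprocessing follows the stated rules", {
  x <- matrix(c(10, 20, 30), 3, 1, dimnames = list(NULL, "a"))
  pp <- preprocess_clinical(x)
  expect_equal(as.vector(pp$x), c(0, 0.5, 1))

  x2 <- matrix(c(10, NA, 30), 3, 1, dimnames = list(NULL, "a"))
  pp2 <- preprocess_clinical(x2)
  expect_equal(as.vector(pp2$x), c(0, 0.5, 1))  # NA -> mean 20 -> 0.5

  x3 <- matrix(c(5, 5, 5), 3, 1, dimnames = list(NULL, "a"))
  expect_equal(as.vector(preprocess_clinical(x3)$x), c(0, 0, 0))

  x4 <- matrix(NA_real_, 3, 1, dimnames = list(NULL, "badcol"))
  expect_error(preprocess_clinical(x4), "badcol")
})

test_that("held-out values outside the training range are clamped", {
  x <- matrix(c(10, 20, 30, 50), 4, 1, dimnames = list(NULL, "a"))
  pp <- preprocess_clinical(x, train_rows = 1:3)
  expect_equal(as.vector(pp$x), c(0, 0.5, 1, 1))
  expect_true(all(pp$x[1:3, ] >= 0 & pp$x[1:3, ] <= 1))
})

test_that("class weights match the inverse-frequency rule", {
  y <- c(rep(0, 84), rep(1, 16))
  cw <- class_weights(y)
  expect_equal(cw$positive_scale, 5.25)
  expect_equal(unname(cw$class_weights["0"] * 84), unname(cw$class_weights["1"] * 16))
  bal <- class_weights(rep(c(0, 1), 20))
  expect_true(all(bal$weights == 1))
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("a strong nonlinear interaction selects a tree family over logistic", {
  for (sd in 1:5) {
    set.seed(sd)
    n <- 400L
    co <- data.frame(patient_id = sprintf("X%04d", 1:n),
                     age = runif(n, -1, 1), bmi = runif(n, -1, 1),
                     her2 = rbinom(n, 1, .5), histological_type = sample(1:4, n, TRUE),
                     progesterone = rbinom(n, 1, .5), mitotic_index = rpois(n, 4),
                     ki67 = runif(n, 1, 60), tumor_grade = sample(1:3, n, TRUE),
                     cancer_subtype = sample(1:4, n, TRUE),
                     tumor_size_mm = runif(n, 10, 60), stringsAsFactors = FALSE)
    # XOR-style signal: linear logistic regression is misspecified
    p <- plogis(3.5 * sign(co$age) * sign(co$bmi))
    co$outcome <- rbinom(n, 1, p)
    co$true_outcome <- co$outcome; co$censored <- 0L; co$has_imaging <- 0L
    plan <- make_folds(co, seed = sd)
    fit <- train_select(co, plan, pseudo_label(co, seed = sd), seed = sd)
    expect_true(fit$best %in% c("rf", "xgb"))
    expect_gt(fit$cv_auc[fit$best], fit$cv_auc["logreg"])
  }
})

test_that("pure-noise features give chance-level cross-validation AUC", {
  set.seed(77)
  n <- 500L
  co <- data.frame(patient_id = sprintf("N%04d", 1:n))
  for (f in clinical_feature_names()) co[[f]] <- rnorm(n)
  co$outcome <- rbinom(n, 1, 0.3)
  co$true_outcome <- co$outcome; co$censored <- 0L; co$has_imaging <- 0L
  plan <- make_folds(co, seed = 77)
  fit <- train_select(co, plan, pseudo_label(co, seed = 77),
                      families = c("rf", "logreg"), seed = 77)
  expect_gte(max(fit$cv_auc), 0.4)
  expect_lte(max(fit$cv_auc), 0.6)
})

test_that("model selection is deterministic given seeds", {
  set.seed(9)
  co <- make_cv_cohort(40L, 160L, 30L, seed = 9)
  plan <- make_folds(co, seed = 9)
  ps <- pseudo_label(co, seed = 9)
  f1 <- train_select(co, plan, ps, seed = 9)
  f2 <- train_select(co, plan, ps, seed = 9)
  expect_identical(f1$cv_auc, f2$cv_auc)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$scores, f2$scores)
})

test_that("a feature the model never uses receives zero attribution", {
  set.seed(21)
  x <- cbind(a = runif(40), b = runif(40))
  pred <- function(m) 2 * m[, "a"]          # ignores b entirely
  rep_ <- explain(pred, x, background = x[1:10, ], nperm = 4, seed = 1)
  expect_true(all(rep_$attributions[, "b"] == 0))
})

test_that("attribution efficiency holds exactly for the sampling estimator", {
  set.seed(22)
  x <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  pred <- function(m) plogis(m[, 1] - 2 * m[, 2] + m[, 1] * m[, 3])
  rep_ <- explain(pred, x, background = x, nperm = 3, seed = 2)
  recon <- rowSums(rep_$attributions) + rep_$base_value
  expect_equal(recon, unname(rep_$predictions), tolerance = 1e-10)
})

test_that("single-feature model on two points attributes the full difference", {
  x <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "only"))
  pred <- function(m) 3 * m[, 1] + 1
  rep_ <- explain(pred, x, background = x, nperm = 1, seed = 3)
  expect_equal(rep_$attributions[, 1],
               unname(rep_$predictions - rep_$base_value), tolerance = 1e-12)
})

test_that("exact tree attributions satisfy efficiency on the link scale", {
  set.seed(23)
  x <- matrix(rnorm(600), 150, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(150, 1, plogis(1.5 * x[, 1] - x[, 3]))
  mdl <- mmrecur:::fit_clinical_family("xgb", x, y, seed = 5)
  rep_ <- explain(mdl, x)
  expect_equal(rep_$scale, "logodds")
  recon <- rowSums(rep_$attributions) + rep_$base_value
  expect_equal(recon, qlogis(unname(rep_$predictions)), tolerance = 1e-4)
})

test_that("a dominant BMI effect is recovered at the top of the ranking", {
  hits <- 0L
  for (sd in 1:5) {
    co <- generate_cohort(cohort_spec(
      n = 400L, censoring_rate = 0.3,
      risk_coefs = c(bmi = -1.8, age = 0, her2 = 0, log_volume = 0),
      seed = 300 + sd))
    ps <- pseudo_label(co, seed = sd)
    rep_ <- explain_clinical(co, ps, family = "rf", n_explain = 80L, seed = sd)
    if (rep_$ranking$feature[1] == "bmi") hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
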