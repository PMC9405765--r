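test_that("AUC handles the perfect, null and small-sample cases", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  set.seed(60)
  s <- rnorm(4000); y <- rbinom(4000, 1, 0.3)
  expect_lt(abs(auc(s, y) - 0.5), 0.03)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
  # 8 listed patients against the exhaustive pairwise oracle
  s8 <- c(0.9, 0.8, 0.8, 0.6, 0.55, 0.4, 0.3, 0.1)
  y8 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(auc(s8, y8), auc_bruteforce(s8, y8))
})

test_that("AUC equals the brute-force concordance oracle on random instances", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_identical(auc(s, y), auc_bruteforce(s, y))
  }
})

test_that("bootstrap CI contains the point estimate and narrows with n", {
  widths <- vapply(c(50L, 200L, 800L), function(n) {
    set.seed(62)
    s <- rnorm(n); y <- rbinom(n, 1, plogis(s))
    ac <- auc_ci(s, y, n_boot = 500, seed = 62)
    expect_gte(ac$auc, ac$ci[1]); expect_lte(ac$auc, ac$ci[2])
    ac$ci[2] - ac$ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("a perfect classifier at target 0.90 gives ideal operating metrics", {
  s <- c(rep(0.9, 10), rep(0.1, 20)); y <- c(rep(1, 10), rep(0, 20))
  m <- metrics_at_sensitivity(s, y, 0.90)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, (m$sensitivity + 1) / 2)
  expect_equal(m$npv, 1)
})

test_that("operating-point metrics match exhaustive threshold enumeration", {
  set.seed(63)
  for (i in 1:20) {
    s <- round(runif(30), 2)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    for (tg in c(0.87, 0.90, 0.93)) {
      m <- metrics_at_sensitivity(s, y, tg)
      o <- op_oracle(s, y, tg)
      expect_equal(m$threshold, o$threshold)
      expect_equal(m$sensitivity, o$sens)
      expect_equal(m$specificity, o$spec)
      expect_equal(m$f1, o$f1)
      expect_equal(m$balanced_accuracy, o$bacc)
      expect_equal(m$ppv, o$ppv)
      expect_equal(m$npv, o$npv)
      # identities hold on every produced object
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
      if (!is.na(m$ppv) && m$ppv + m$sensitivity > 0) {
        expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
      }
    }
  }
})

test_that("constant scores degenerate to sensitivity 1, specificity 0", {
  m <- metrics_at_sensitivity(rep(0.5, 20), rep(c(0, 1), 10), 0.9)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
})

test_that("McNemar matches the exact binomial oracle", {
  mk <- function(b, c) {
    # construct paired predictions with exactly b and c discordant cases
    n <- b + c + 10L
    labels <- rep(0L, n)
    pa <- rep(0L, n); pb <- rep(0L, n)
    if (b > 0) pb[1:b] <- 1L                       # a correct, b wrong
    if (c > 0) pa[(b + 1):(b + c)] <- 1L           # a wrong, b correct
    list(pa = pa, pb = pb, labels = labels)
  }
  z <- mk(1L, 1L)
  expect_equal(mcnemar_bonferroni(z$pa, z$pb, z$labels)$p_value, 1)
  z <- mk(10L, 0L)
  r <- mcnemar_bonferroni(z$pa, z$pb, z$labels)
  expect_equal(r$p_value, 2 * 0.5^10, tolerance = 1e-12)
  expect_true(r$significant)       # 0.001953 < 0.0042
  z <- mk(5L, 3L)
  r <- mcnemar_bonferroni(z$pa, z$pb, z$labels)
  expect_equal(r$p_value, mcnemar_oracle(5, 3), tolerance = 1e-12)
  expect_false(r$significant)
  # large discordance switches to the continuity-corrected chi-squared form
  z <- mk(20L, 15L)
  r <- mcnemar_bonferroni(z$pa, z$pb, z$labels)
  expect_equal(r$method, "chisq_cc")
  ref <- stats::mcnemar.test(matrix(c(0, 15, 20, 0), 2, 2))$p.value
  expect_equal(r$p_value, ref)
  expect_error(mcnemar_bonferroni(1:3, 1:4, 1:3), "lengths differ")
})

test_that("the subgroup scan enumerates exactly 432 candidate cells", {
  co <- generate_cohort(cohort_spec(n = 300L, seed = 70))
  sc <- data.frame(patient_id = co$patient_id, score = runif(300))
  t0 <- proc.time()
  sg <- subgroup_scan(co, sc, n_boot = 50, seed = 70)
  expect_equal(sg$n_candidates, 432L)
  expect_equal(nrow(sg$cells), 432L)
  expect_lt((proc.time() - t0)[3], 60)
})

test_that("subgroup cells below the size or outcome thresholds are excluded", {
  set.seed(71)
  co <- make_cv_cohort(30L, 120L, 0L, seed = 71)
  # cell A: 9 patients (too few); cell B: 12 patients, all negative
  co$age[1:9] <- 45; co$cancer_subtype[1:9] <- 1L; co$histological_type[1:9] <- 1L
  co$tumor_grade[1:9] <- 3L; co$ki67[1:9] <- 50
  sc <- data.frame(patient_id = co$patient_id, score = runif(nrow(co)))
  sg <- subgroup_scan(co, sc, n_boot = 20, seed = 71)
  cells <- sg$cells
  cellA <- cells[cells$age == "<=50" & cells$cancer_subtype == "TNBC" &
                   cells$histological_type == "NST" & cells$tumor_grade == "III" &
                   cells$ki67 == ">15", ]
  if (cellA$n == 9) expect_false(cellA$analyzed)
  all_neg <- cells[cells$n >= 10 & cells$n_pos == 0, ]
  if (nrow(all_neg)) expect_true(all(!all_neg$analyzed))
  analyzed <- cells[cells$analyzed, ]
  expect_true(all(analyzed$n >= 10 & analyzed$n_pos >= 1 & analyzed$n_neg >= 1))
  # sorted by AUC descending among analyzed cells
  expect_true(all(diff(analyzed$auc) <= 1e-12))
})

test_that("subgroup membership is reproducible from the level definitions", {
  co <- generate_cohort(cohort_spec(n = 400L, seed = 72))
  sc <- data.frame(patient_id = co$patient_id, score = runif(400))
  sg <- subgroup_scan(co, sc, n_boot = 20, seed = 72)
  levs <- subgroup_levels()
  d <- merge(co, sc, by = "patient_id")
  d <- d[d$censored == 0L & !is.na(d$outcome), ]
  # re-derive membership for the top analyzed cell
  top <- sg$cells[sg$cells$analyzed, ][1, ]
  member <- rep(TRUE, nrow(d))
  for (f in names(levs)) member <- member & levs[[f]][[top[[f]]]](d)
  expect_equal(sum(d$outcome[member] == 1), top$n_pos)
  expect_equal(sum(d$outcome[member] == 0), top$n_neg)
  expect_equal(auc(d$score[member], d$outcome[member]), top$auc)
})

test_that("age band boundaries follow the declared convention", {
  d <- data.frame(age = c(50, 55, 60, NA))
  levs <- subgroup_levels()$age
  expect_equal(levs[["<=50"]](d), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(levs[["50-60"]](d), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(levs[[">=60"]](d), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(levs[["missing"]](d), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("ROC coordinates integrate back to the rank AUC", {
  set.seed(74)
  s <- rnorm(150); y <- rbinom(150, 1, plogis(s))
  rc <- roc_coordinates(s, y)
  expect_equal(rc$sensitivity[1], 0); expect_equal(rc$specificity[1], 1)
  expect_equal(rev(rc$sensitivity)[1], 1)
  fpr <- 1 - rc$specificity
  trap <- sum(diff(fpr) * (utils::head(rc$sensitivity, -1) +
                             utils::tail(rc$sensitivity, -1)) / 2)
  expect_equal(trap, auc(s, y), tolerance = 1e-10)
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(auc(s, y), ref, tolerance = 1e-12)
})
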