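#' ROC AUC (rank statistic)
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted one half (Mann-Whitney formulation).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with percentile-bootstrap confidence interval
#'
#' Class-stratified resampling of patients, percentile interval of the
#' bootstrap AUC distribution.
#'
#' @param scores,labels as in [auc()].
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `auc`, `ci` (length 2), `n_boot`, `n_pos`, `n_neg`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  point <- auc(scores, labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bi <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
              neg[sample.int(length(neg), length(neg), replace = TRUE)])
      auc(scores[bi], labels[bi])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  list(auc = point, ci = unname(stats::quantile(boots, c(a, 1 - a))),
       n_boot = as.integer(n_boot), n_pos = length(pos), n_neg = length(neg))
}

#' Metrics at a fixed sensitivity operating point
#'
#' The threshold is the largest score threshold whose sensitivity reaches
#' the target (predicting positive at score >= threshold); among equal
#' sensitivities this automatically selects the highest specificity.
#' Specificity, F1, balanced accuracy, PPV and NPV are read from the
#' resulting confusion matrix. Balanced accuracy is exactly
#' (sensitivity + specificity)/2.
#'
#' @param scores,labels as in [auc()].
#' @param target target sensitivity (the study's clinically interesting
#'   points are 0.87, 0.90 and 0.93).
#' @return object of class `operating_point_metrics`.
#' @export
metrics_at_sensitivity <- function(scores, labels, target) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("metrics_at_sensitivity: both classes must be present", call. = FALSE)
  }
  thr_cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr_cand, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  ok <- which(sens >= target)
  if (length(ok) == 0L) {
    warning("metrics_at_sensitivity: target sensitivity unreachable; using the ",
            "lowest threshold")
    thr <- min(thr_cand)
  } else {
    thr <- thr_cand[min(ok)]  # candidates sorted descending: first hit = largest
  }
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  sens_a <- tp / n1; spec <- tn / n0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (is.na(ppv) || ppv + sens_a == 0) 0 else 2 * ppv * sens_a / (ppv + sens_a)
  structure(list(target = target, threshold = thr, sensitivity = sens_a,
                 specificity = spec, f1 = f1,
                 balanced_accuracy = (sens_a + spec) / 2,
                 ppv = ppv, npv = npv,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "operating_point_metrics")
}

#' McNemar comparison of two classifiers with Bonferroni correction
#'
#' Paired test on the discordant counts b (A correct, B wrong) and c
#' (A wrong, B correct): the exact two-sided binomial test when
#' b + c < 25, the continuity-corrected chi-squared form otherwise.
#' Significance is declared at `alpha / n_tests` (the study's setting,
#' alpha = 0.05 over 12 tests, gives 0.0042).
#'
#' @param preds_a,preds_b binary predictions on the same patients.
#' @param labels true binary labels.
#' @param n_tests number of hypotheses for Bonferroni correction.
#' @param alpha family-wise error level.
#' @return list with `p_value`, `significant`, discordant counts, the
#'   corrected threshold and the method used.
#' @export
mcnemar_bonferroni <- function(preds_a, preds_b, labels, n_tests = 12L,
                               alpha = 0.05) {
  if (length(preds_a) != length(preds_b) || length(preds_a) != length(labels)) {
    stop("mcnemar_bonferroni: prediction and label lengths differ", call. = FALSE)
  }
  a_ok <- preds_a == labels; b_ok <- preds_b == labels
  b <- sum(a_ok & !b_ok); cc <- sum(!a_ok & b_ok)
  if (b + cc == 0L) {
    p <- 1; method <- "exact"
  } else if (b + cc < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact"
  } else {
    p <- stats::mcnemar.test(matrix(c(0, cc, b, 0), 2, 2), correct = TRUE)$p.value
    method <- "chisq_cc"
  }
  thr <- alpha / n_tests
  list(p_value = p, significant = p < thr, b = b, c = cc,
       threshold = thr, method = method)
}

#' Prognostic subgroup level definitions
#'
#' The five stratification features and their levels (each including a
#' missing level): age bands <=50, (50, 60), >=60 (a patient aged exactly
#' 60 falls in >=60); cancer subtype luminal (Luminal A or B), TNBC,
#' HER2+; histological type NST vs other; tumor grade I-II vs III; Ki67
#' <=15% vs >15%. Level-domain sizes 4, 4, 3, 3, 3.
#'
#' @return named list of level-membership functions per feature.
#' @export
subgroup_levels <- function() {
  list(
    age = list(
      "<=50" = function(d) !is.na(d$age) & d$age <= 50,
      "50-60" = function(d) !is.na(d$age) & d$age > 50 & d$age < 60,
      ">=60" = function(d) !is.na(d$age) & d$age >= 60,
      "missing" = function(d) is.na(d$age)),
    cancer_subtype = list(
      "luminal" = function(d) !is.na(d$cancer_subtype) & d$cancer_subtype %in% c(2, 3),
      "TNBC" = function(d) !is.na(d$cancer_subtype) & d$cancer_subtype == 1,
      "HER2+" = function(d) !is.na(d$cancer_subtype) & d$cancer_subtype == 4,
      "missing" = function(d) is.na(d$cancer_subtype)),
    histological_type = list(
      "NST" = function(d) !is.na(d$histological_type) & d$histological_type == 1,
      "other" = function(d) !is.na(d$histological_type) & d$histological_type != 1,
      "missing" = function(d) is.na(d$histological_type)),
    tumor_grade = list(
      "I-II" = function(d) !is.na(d$tumor_grade) & d$tumor_grade <= 2,
      "III" = function(d) !is.na(d$tumor_grade) & d$tumor_grade == 3,
      "missing" = function(d) is.na(d$tumor_grade)),
    ki67 = list(
      "<=15" = function(d) !is.na(d$ki67) & d$ki67 <= 15,
      ">15" = function(d) !is.na(d$ki67) & d$ki67 > 15,
      "missing" = function(d) is.na(d$ki67))
  )
}

#' Combinatorial prognostic subgroup scan
#'
#' Enumerates all 432 (4 x 4 x 3 x 3 x 3) candidate subgroup cells over
#' the level definitions of [subgroup_levels()], analyzes every cell with
#' at least `min_n` patients and at least one positive and one negative
#' outcome, computes AUC with a bootstrap confidence interval per analyzed
#' cell, and returns the table sorted by AUC (descending) with the
#' analyzed cells first. Input scores must already be restricted to
#' uncensored patients.
#'
#' @param cohort cohort data.frame (uncensored evaluation view).
#' @param scores data.frame with `patient_id` and `score`.
#' @param min_n minimum patients per analyzed cell (default 10).
#' @param n_boot,seed bootstrap controls for the per-cell CI.
#' @return object of class `subgroup_scan`: `cells` (one row per
#'   candidate), `n_candidates`, `n_analyzed`.
#' @export
subgroup_scan <- function(cohort, scores, min_n = 10L, n_boot = 2000L, seed = 1L) {
  d <- merge(cohort, scores, by = "patient_id")
  d <- d[d$censored == 0L & !is.na(d$outcome), ]
  levs <- subgroup_levels()
  grid <- expand.grid(lapply(levs, names), stringsAsFactors = FALSE)
  names(grid) <- names(levs)
  n_cells <- nrow(grid)
  out <- grid
  out$n <- out$n_pos <- out$n_neg <- 0L
  out$auc <- out$ci_lo <- out$ci_hi <- NA_real_
  out$analyzed <- FALSE
  for (i in seq_len(n_cells)) {
    member <- rep(TRUE, nrow(d))
    for (feat in names(levs)) {
      member <- member & levs[[feat]][[grid[i, feat]]](d)
    }
    n_pos <- sum(d$outcome[member] == 1L); n_neg <- sum(d$outcome[member] == 0L)
    out$n[i] <- n_pos + n_neg; out$n_pos[i] <- n_pos; out$n_neg[i] <- n_neg
    if (n_pos + n_neg >= min_n && n_pos >= 1L && n_neg >= 1L) {
      ac <- auc_ci(d$score[member], d$outcome[member], n_boot = n_boot,
                   seed = derive_seed(seed, paste0("cell", i)))
      out$auc[i] <- ac$auc; out$ci_lo[i] <- ac$ci[1]; out$ci_hi[i] <- ac$ci[2]
      out$analyzed[i] <- TRUE
    }
  }
  out <- out[order(!out$analyzed, -ifelse(is.na(out$auc), -Inf, out$auc)), ]
  structure(list(cells = out, n_candidates = n_cells,
                 n_analyzed = sum(out$analyzed)),
            class = "subgroup_scan")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level.
#' @param n_tests number of tests.
#' @return the per-test threshold alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 12L) alpha / n_tests
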