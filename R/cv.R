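#' Stratified, cross-cohort-correlated fold assignment
#'
#' Uncensored patients are stratified jointly by outcome and imaging
#' availability (round-robin within each stratum after a seeded shuffle),
#' so positive counts per fold differ by at most one among uncensored
#' patients in the full cohort *and* in its imaging subset — a patient with
#' imaging keeps the same fold in both cohorts by construction. Censored
#' patients are spread across folds round-robin — in side-model score
#' order when scores are supplied, so training folds stay comparable.
#'
#' @param cohort cohort data.frame with `patient_id`, `outcome`,
#'   `censored`, `has_imaging`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param side_scores optional data.frame (`patient_id`, `side_score`) used
#'   to stratify censored patients.
#' @return object of class `fold_plan`: `patient_id`, `fold`, per-fold
#'   count table, `k`, `seed`.
#' @export
make_folds <- function(cohort, k = 5L, seed = 1L, side_scores = NULL) {
  stopifnot(all(c("patient_id", "outcome", "censored") %in% names(cohort)))
  has_img <- if ("has_imaging" %in% names(cohort)) cohort$has_imaging else 0L
  unc_pos <- sum(cohort$censored == 0L & cohort$outcome == 1L, na.rm = TRUE)
  if (unc_pos < k) {
    stop(sprintf("make_folds: %d uncensored positives are too few for %d folds",
                 unc_pos, k), call. = FALSE)
  }
  n <- nrow(cohort)
  fold <- integer(n)
  with_seed(seed, {
    cls <- ifelse(cohort$censored == 1L, "cens", paste0("out", cohort$outcome))
    img_lab <- ifelse(has_img == 1L, "img", "noimg")
    for (cl in unique(cls)) {
      # round-robin continues its rotation across the imaging/non-imaging
      # strata of one outcome class: counts then balance to +-1 both within
      # the imaging subset and in the combined cohort
      ptr <- sample.int(k, 1L) - 1L
      for (im in c("img", "noimg")) {
        rows <- which(cls == cl & img_lab == im)
        if (!length(rows)) next
        if (cl == "cens" && !is.null(side_scores)) {
          sc <- side_scores$side_score[match(cohort$patient_id[rows],
                                             side_scores$patient_id)]
          rows <- rows[order(sc, sample.int(length(rows)))]
        } else {
          rows <- rows[sample.int(length(rows))]
        }
        fold[rows] <- (ptr + seq_along(rows) - 1L) %% k + 1L
        ptr <- (ptr + length(rows)) %% k
      }
    }
  })
  counts <- table(fold = fold,
                  class = ifelse(cohort$censored == 1L, "censored",
                                 paste0("outcome", cohort$outcome)))
  structure(list(patient_id = cohort$patient_id, fold = fold,
                 counts = counts, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_plan")
}

#' Side-model pseudo-labels for censored patients
#'
#' A random forest side model is trained on the uncensored patients'
#' clinical features (mean-imputed, class-weighted) and its predicted
#' probability is thresholded at 0.5 to give every censored patient a
#' binary training label. Censored patients never enter any validation or
#' evaluation set; the pseudo-label only substitutes for the unobservable
#' outcome during training. With `per_fold = TRUE` a stricter variant
#' trains one side model per fold, using only uncensored patients outside
#' that validation fold to label the censored patients of the remaining
#' training folds.
#'
#' @param cohort cohort data.frame.
#' @param plan a [make_folds()] plan (required for `per_fold = TRUE`).
#' @param features feature columns used by the side model.
#' @param seed integer seed.
#' @param per_fold train one side model per validation fold.
#' @param threshold score threshold for the binary pseudo-label.
#' @return data.frame (class `pseudo_label_set`) with `patient_id`,
#'   `side_score`, `pseudo_label` — one row per censored patient (zero rows
#'   when the cohort has none). For `per_fold = TRUE`, one row per censored
#'   patient and fold, with a `fold` column naming the validation fold
#'   whose training data the label is for.
#' @export
pseudo_label <- function(cohort, plan = NULL, features = clinical_feature_names(),
                         seed = 1L, per_fold = FALSE, threshold = 0.5) {
  cens <- which(cohort$censored == 1L)
  empty <- data.frame(patient_id = character(0), side_score = numeric(0),
                      pseudo_label = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("pseudo_label_set", "data.frame")
  if (length(cens) == 0L) return(empty)
  x <- as.matrix(cohort[, features])
  fit_side <- function(train_rows, pred_rows, fit_seed) {
    imp <- impute_by_train_means(x, train_rows)
    y <- factor(cohort$outcome[train_rows], levels = c(0, 1))
    w <- class_weights(cohort$outcome[train_rows])$weights
    d <- data.frame(imp$x[train_rows, , drop = FALSE])
    rf <- ranger::ranger(y = y, x = d, num.trees = 500, probability = TRUE,
                         case.weights = w, seed = fit_seed, num.threads = 1)
    stats::predict(rf, data.frame(imp$x[pred_rows, , drop = FALSE]),
                   num.threads = 1)$predictions[, "1"]
  }
  if (!per_fold) {
    unc <- which(cohort$censored == 0L)
    s <- fit_side(unc, cens, derive_seed(seed, "side"))
    out <- data.frame(patient_id = cohort$patient_id[cens], side_score = s,
                      pseudo_label = as.integer(s >= threshold),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(plan, "fold_plan"))
    fold <- plan$fold[match(cohort$patient_id, plan$patient_id)]
    out <- NULL
    for (f in seq_len(plan$k)) {
      unc <- which(cohort$censored == 0L & fold != f)
      pred <- cens[fold[cens] != f]
      if (!length(pred)) next
      s <- fit_side(unc, pred, derive_seed(seed, paste0("side", f)))
      out <- rbind(out, data.frame(patient_id = cohort$patient_id[pred],
                                   side_score = s,
                                   pseudo_label = as.integer(s >= threshold),
                                   fold = f, stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}
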