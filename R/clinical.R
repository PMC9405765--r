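#' Min-max scaling fitted on training rows
#'
#' Scales every feature to the [0, 1] range using training minima and
#' maxima. Values of held-out data falling outside the training range are
#' clamped to [0, 1] after scaling; constant columns scale to zero.
#'
#' @param x numeric matrix of training rows (NA-free).
#' @return scaling statistics (class `minmax_scaler`).
#' @export
fit_minmax <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  structure(list(lo = lo, hi = hi), class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler a fitted `minmax_scaler`.
#' @param newx matrix to transform.
#' @export
apply_minmax <- function(scaler, newx) {
  rng <- scaler$hi - scaler$lo
  out <- sweep(newx, 2, scaler$lo, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Preprocess a clinical feature table
#'
#' The tabular preprocessing chain: mean imputation (means computed on the
#' raw training rows, before scaling) followed by min-max scaling to
#' [0, 1], both fitted on training rows only. A column that is entirely
#' missing in training errors, naming the column.
#'
#' @param x numeric matrix (cohort rows x features, NAs allowed).
#' @param train_rows logical or integer index of training rows.
#' @param stats optional previously fitted statistics (reapply mode).
#' @return list with `x` (transformed full matrix), `stats` (imputation
#'   means + scaler, class `clinical_preproc`).
#' @export
preprocess_clinical <- function(x, train_rows = seq_len(nrow(x)), stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    imp <- impute_by_train_means(x, train_rows)
    scaler <- fit_minmax(imp$x[train_rows, , drop = FALSE])
    stats <- structure(list(means = imp$means, scaler = scaler),
                       class = "clinical_preproc")
    xi <- imp$x
  } else {
    xi <- x
    for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- stats$means[j]
  }
  list(x = apply_minmax(stats$scaler, xi), stats = stats)
}

#' Class-balancing weights
#'
#' Per-sample weights inversely proportional to class frequencies,
#' `w(class c) = n_total / (2 n_c)` (so weights times counts are identical
#' across classes), plus the gradient-boosting positive scale factor
#' `n_neg / n_pos`.
#'
#' @param labels binary 0/1 vector (both classes must be present).
#' @return list with `weights` (per sample), `class_weights` (length 2)
#'   and `positive_scale`.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels); n1 <- sum(labels == 1L); n0 <- n - n1
  if (n0 == 0L || n1 == 0L) {
    stop("class_weights: both classes must be present", call. = FALSE)
  }
  cw <- c(`0` = n / (2 * n0), `1` = n / (2 * n1))
  list(weights = unname(cw[as.character(labels)]), class_weights = cw,
       positive_scale = n0 / n1)
}

# one clinical classifier family on preprocessed features
fit_clinical_family <- function(family, x, y, seed) {
  w <- class_weights(y)
  switch(family,
    rf = {
      ranger::ranger(y = factor(y, levels = c(0, 1)), x = data.frame(x),
                     num.trees = 500, mtry = max(1L, floor(sqrt(ncol(x)))),
                     probability = TRUE, case.weights = w$weights,
                     seed = seed, num.threads = 1)
    },
    logreg = {
      # ridge-penalized logistic matching an L2 C = 1 formulation
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = 1 / nrow(x), weights = w$weights,
                     standardize = FALSE)
    },
    xgb = {
      dtr <- xgboost::xgb.DMatrix(x, label = y)
      with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4, eta = 0.05,
                      scale_pos_weight = w$positive_scale, nthread = 1,
                      seed = seed),
        data = dtr, nrounds = 300, verbose = 0))
    },
    stop("unknown classifier family: ", family))
}

predict_clinical_family <- function(model, x) {
  if (inherits(model, "ranger")) {
    stats::predict(model, data.frame(x), num.threads = 1)$predictions[, "1"]
  } else if (inherits(model, "glmnet")) {
    as.vector(stats::predict(model, x, type = "response"))
  } else {
    stats::predict(model, xgboost::xgb.DMatrix(x))
  }
}

#' Train candidate clinical classifiers and select the best family
#'
#' Random forest, ridge logistic regression and gradient boosting are each
#' trained with censoring-aware 5-fold cross-validation (censored patients
#' carry side-model pseudo-labels in training folds; validation folds are
#' uncensored only) with class-imbalance handling, and the family with the
#' best mean cross-validation AUC is selected. Preprocessing statistics are
#' fitted on training folds only.
#'
#' @param cohort cohort data.frame.
#' @param plan a [make_folds()] plan.
#' @param pseudo a [pseudo_label()] result.
#' @param features clinical feature columns.
#' @param families candidate families.
#' @param seed training seed.
#' @return object of class `clinical_fit`: per-family fold-models,
#'   out-of-fold `scores` per family, mean CV AUC per family, `best`
#'   (selected family name) and an audit trail of training IDs.
#' @export
train_select <- function(cohort, plan, pseudo, features = clinical_feature_names(),
                         families = c("rf", "logreg", "xgb"), seed = 1L) {
  x <- as.matrix(cohort[, features])
  fold <- plan$fold[match(cohort$patient_id, plan$patient_id)]
  lab <- cohort$outcome
  if (nrow(pseudo)) {
    pl <- pseudo$pseudo_label[match(cohort$patient_id, pseudo$patient_id)]
    lab[cohort$censored == 1L] <- pl[cohort$censored == 1L]
  }
  folds <- sort(unique(fold))
  fits <- list(); oof <- list(); cv_auc <- numeric(0)
  for (fam in families) {
    fam_models <- list(); sc <- NULL; aucs <- numeric(0)
    for (f in folds) {
      tr <- which(fold != f & !is.na(lab))
      va <- which(fold == f & cohort$censored == 0L)
      pp <- preprocess_clinical(x, tr)
      mdl <- fit_clinical_family(fam, pp$x[tr, , drop = FALSE], lab[tr],
                                 derive_seed(seed, paste0(fam, f)))
      p <- predict_clinical_family(mdl, pp$x[va, , drop = FALSE])
      fam_models[[as.character(f)]] <- list(model = mdl, stats = pp$stats,
                                            fold = f,
                                            train_ids = cohort$patient_id[tr])
      sc <- rbind(sc, data.frame(patient_id = cohort$patient_id[va], fold = f,
                                 score = p, stringsAsFactors = FALSE))
      aucs <- c(aucs, auc(p, cohort$outcome[va]))
    }
    fits[[fam]] <- fam_models
    oof[[fam]] <- sc
    cv_auc[fam] <- mean(aucs)
  }
  best <- names(cv_auc)[which.max(cv_auc)]
  structure(list(fits = fits, scores = oof, cv_auc = cv_auc, best = best,
                 features = features, seed = seed, modality = "clinical"),
            class = "clinical_fit")
}

#' Score patients with the selected clinical model (holdout rule)
#'
#' Mean of the five fold-models of the given family.
#' @param fit a `clinical_fit`.
#' @param cohort cohort rows to score.
#' @param family model family (default the selected best).
#' @return data.frame with `patient_id` and `score`.
#' @export
predict_clinical_holdout <- function(fit, cohort, family = fit$best) {
  x <- as.matrix(cohort[, fit$features])
  scores <- sapply(fit$fits[[family]], function(m) {
    pp <- preprocess_clinical(x, stats = m$stats)
    predict_clinical_family(m$model, pp$x)
  })
  data.frame(patient_id = cohort$patient_id,
             score = rowMeans(matrix(scores, nrow = nrow(cohort))),
             stringsAsFactors = FALSE)
}
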