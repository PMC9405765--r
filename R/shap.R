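#' Permutation-sampling Shapley attributions
#'
#' Model-agnostic Shapley value estimation by permutation sampling with a
#' background reference set: for each sampled feature ordering, features
#' are switched one at a time from background values to the explained
#' instance's values and the change in the mean model output is credited
#' to the switched feature. The telescoping sum makes the attribution
#' exactly efficient for every permutation: attributions sum to
#' `f(x) - mean(f(background))` regardless of the number of permutations.
#'
#' @param pred_fun function(matrix) -> numeric scores.
#' @param x matrix of instances to explain.
#' @param background matrix of background rows (marginal reference).
#' @param nperm number of sampled permutations.
#' @param seed integer seed.
#' @return list with `attributions` (matrix like `x`) and `base_value`
#'   (mean background prediction).
#' @export
shap_sampling <- function(pred_fun, x, background, nperm = 8L, seed = 1L) {
  x <- as.matrix(x); background <- as.matrix(background)
  p <- ncol(x); n <- nrow(x); nb <- nrow(background)
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  base <- mean(pred_fun(background))
  with_seed(seed, {
    for (it in seq_len(nperm)) {
      ord <- sample.int(p)
      # build all hybrid rows for this permutation in one batch:
      # stage s = background with features ord[1..s] taken from x
      big <- matrix(0, n * nb * (p + 1L), p)
      row0 <- 0L
      for (s in 0:p) {
        hy <- background[rep(seq_len(nb), times = n), , drop = FALSE]
        take <- ord[seq_len(s)]
        if (s > 0) {
          xi <- x[rep(seq_len(n), each = nb), take, drop = FALSE]
          hy[, take] <- xi
        }
        big[row0 + seq_len(n * nb), ] <- hy
        row0 <- row0 + n * nb
      }
      colnames(big) <- colnames(x)
      pr <- pred_fun(big)
      dim(pr) <- c(nb, n, p + 1L)
      stage_mean <- apply(pr, c(2, 3), mean)        # n x (p+1)
      contrib <- stage_mean[, -1L, drop = FALSE] - stage_mean[, -(p + 1L), drop = FALSE]
      phi[, ord] <- phi[, ord] + contrib / nperm
    }
  })
  list(attributions = phi, base_value = base)
}

#' Feature attributions for a fitted model
#'
#' Exact TreeSHAP for gradient-boosting models (on the log-odds scale);
#' permutation-sampling Shapley values (on the probability scale) for
#' every other model or for an arbitrary prediction function.
#'
#' @param model a fitted model (`xgb.Booster`, `ranger`, `glmnet`) or a
#'   prediction function.
#' @param x matrix of instances to explain.
#' @param background background matrix for the sampling estimator (ignored
#'   by the exact tree path).
#' @param nperm,seed sampling controls.
#' @return an `attribution_report`: per-instance attributions, base value,
#'   predictions, global ranking by mean absolute attribution, and the
#'   top-10 feature list.
#' @export
explain <- function(model, x, background = x, nperm = 8L, seed = 1L) {
  x <- as.matrix(x)
  if (inherits(model, "xgb.Booster")) {
    ctr <- stats::predict(model, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
    p <- ncol(ctr) - 1L
    res <- list(attributions = ctr[, seq_len(p), drop = FALSE],
                base_value = ctr[1, p + 1L])
    preds <- stats::predict(model, xgboost::xgb.DMatrix(x))
    scale <- "logodds"
  } else {
    pred_fun <- if (is.function(model)) model else
      function(m) predict_clinical_family(model, m)
    res <- shap_sampling(pred_fun, x, background, nperm = nperm, seed = seed)
    preds <- pred_fun(x)
    scale <- "probability"
  }
  attribution_report(res$attributions, res$base_value, preds, scale)
}

#' @rdname explain
#' @param attributions,base_value,predictions,scale report components.
#' @export
attribution_report <- function(attributions, base_value, predictions, scale) {
  mean_abs <- colMeans(abs(attributions))
  ranking <- data.frame(feature = colnames(attributions), mean_abs = mean_abs,
                        row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs), ]
  structure(list(attributions = attributions, base_value = base_value,
                 predictions = predictions, scale = scale,
                 ranking = ranking,
                 top10 = utils::head(ranking$feature, 10L)),
            class = "attribution_report")
}

#' Explain the clinical model on the whole cohort
#'
#' Mirrors the study's explanation protocol: one model of the selected
#' family is trained on the entire cohort (uncensored outcomes plus
#' side-model pseudo-labels for censored patients, full-cohort
#' preprocessing) and explained on a subset of patients. With
#' `complete_cases = TRUE` the model is refit and explained on the
#' complete-case subset only — the missing-value robustness re-run.
#'
#' @param cohort cohort data.frame.
#' @param pseudo a [pseudo_label()] result.
#' @param family classifier family (typically the selected best).
#' @param features feature columns.
#' @param n_explain number of patients to explain (sampling estimator
#'   cost control).
#' @param n_background background rows for the sampling estimator.
#' @param nperm,seed sampling controls.
#' @param complete_cases restrict to patients without missing values.
#' @return an `attribution_report`.
#' @export
explain_clinical <- function(cohort, pseudo, family = "rf",
                             features = clinical_feature_names(),
                             n_explain = 150L, n_background = 16L,
                             nperm = 4L, seed = 1L, complete_cases = FALSE) {
  if (complete_cases) {
    cohort <- cohort[stats::complete.cases(cohort[, features]), ]
  }
  lab <- cohort$outcome
  if (nrow(pseudo)) {
    pl <- pseudo$pseudo_label[match(cohort$patient_id, pseudo$patient_id)]
    lab[cohort$censored == 1L] <- pl[cohort$censored == 1L]
  }
  keep <- !is.na(lab)
  x <- as.matrix(cohort[keep, features]); lab <- lab[keep]
  pp <- preprocess_clinical(x)
  mdl <- fit_clinical_family(family, pp$x, lab, derive_seed(seed, "explain_fit"))
  rows <- with_seed(derive_seed(seed, "explain_rows"),
                    sample.int(nrow(pp$x), min(n_explain, nrow(pp$x))))
  bg <- with_seed(derive_seed(seed, "explain_bg"),
                  pp$x[sample.int(nrow(pp$x), min(n_background, nrow(pp$x))), ,
                       drop = FALSE])
  explain(mdl, pp$x[rows, , drop = FALSE], background = bg,
          nperm = nperm, seed = derive_seed(seed, "explain_perm"))
}
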