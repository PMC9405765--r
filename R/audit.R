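## Integrity audits run after every pipeline execution. Each returns TRUE
## or a character description of the violation.

#' Audit: no censored patient in any evaluation set
#'
#' @param score_ids patient IDs that received evaluation scores.
#' @param cohort cohort data.frame.
#' @return TRUE, or a message describing the violation.
#' @export
audit_evaluation_purity <- function(score_ids, cohort) {
  cens <- cohort$patient_id[cohort$censored == 1L]
  bad <- intersect(score_ids, cens)
  if (length(bad) == 0L) TRUE else
    paste("censored patients present in evaluation set:",
          paste(utils::head(bad), collapse = ", "))
}

#' Audit: no patient scored by a model trained on their fold
#'
#' Checks the out-of-fold score table of a fit against the recorded
#' training IDs of the producing fold-model.
#'
#' @param fit a `clinical_fit` (one family is audited per call, via
#'   `family`) or an `mpmri_fit`.
#' @param family for `clinical_fit`, the family whose models to audit.
#' @return TRUE or a violation message.
#' @export
audit_no_leakage <- function(fit, family = NULL) {
  if (inherits(fit, "clinical_fit")) {
    family <- family %||% fit$best
    models <- fit$fits[[family]]
    scores <- fit$scores[[family]]
  } else {
    models <- fit$models
    scores <- fit$scores
  }
  for (i in seq_len(nrow(scores))) {
    m <- models[[as.character(scores$fold[i])]]
    if (scores$patient_id[i] %in% m$train_ids) {
      return(paste("patient", scores$patient_id[i],
                   "scored by a model trained on their fold", scores$fold[i]))
    }
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit: cross-cohort fold correlation and stratification
#'
#' Verifies that every imaging patient's fold equals their fold in the
#' full clinical cohort (the plan must cover both views identically) and
#' that per-fold uncensored positive counts differ by at most one, both
#' overall and within the imaging subset.
#'
#' @param plan a [make_folds()] plan.
#' @param cohort cohort data.frame.
#' @return TRUE or a violation message.
#' @export
audit_fold_correlation <- function(plan, cohort) {
  fold <- plan$fold[match(cohort$patient_id, plan$patient_id)]
  if (any(is.na(fold))) return("patients missing from the fold plan")
  check_strat <- function(rows, label) {
    pos <- table(factor(fold[rows], levels = seq_len(plan$k)))
    if (diff(range(pos)) > 1L)
      paste("per-fold positive counts differ by more than 1 in", label) else TRUE
  }
  r1 <- check_strat(which(cohort$censored == 0L & cohort$outcome == 1L), "full cohort")
  if (!isTRUE(r1)) return(r1)
  img <- which(cohort$censored == 0L & cohort$outcome == 1L & cohort$has_imaging == 1L)
  if (length(img)) {
    r2 <- check_strat(img, "imaging subset")
    if (!isTRUE(r2)) return(r2)
  }
  TRUE
}

#' Audit: calibration preserves ranking (AUC unchanged)
#'
#' @param raw,calibrated paired score vectors.
#' @param labels binary labels.
#' @param tol numerical tolerance.
#' @return TRUE or a violation message.
#' @export
audit_calibration_rank <- function(raw, calibrated, labels, tol = 1e-12) {
  d <- abs(auc(raw, labels) - auc(calibrated, labels))
  if (d <= tol) TRUE else sprintf("calibrated AUC differs from raw AUC by %g", d)
}
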