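#' ROC curve coordinates
#'
#' Sensitivity/specificity at every distinct threshold, for plotting and
#' export.
#'
#' @param scores,labels as in [auc()].
#' @return data.frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_coordinates <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = thr,
             sensitivity = vapply(thr, function(t)
               sum(scores >= t & labels == 1L) / n1, numeric(1)),
             specificity = vapply(thr, function(t)
               sum(scores < t & labels == 0L) / n0, numeric(1)))
}

#' Write the pipeline's evaluation artifacts to disk
#'
#' Plain-text export of a [run_recurrence_pipeline()] result: an
#' evaluation summary (AUCs with CIs, operating-point metrics grid,
#' McNemar comparisons, calibrator parameters, audit status) as JSON; the
#' per-patient score table (raw, calibrated, ensemble) as CSV; the fold
#' plan and pseudo-label set as CSV; the attribution matrix as CSV with a
#' JSON ranking; ROC coordinates of the ensemble as CSV; and, when
#' present, the subgroup table as CSV.
#'
#' @param res a `recurrence_pipeline` result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(res, dir) {
  stopifnot(inherits(res, "recurrence_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  w <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  w(res$score_table, "scores.csv")
  w(res$ensemble, "ensemble_scores.csv")
  w(data.frame(patient_id = res$plan$patient_id, fold = res$plan$fold),
    "fold_plan.csv")
  w(as.data.frame(res$pseudo), "pseudo_labels.csv")
  if (!is.null(res$attribution)) {
    w(as.data.frame(res$attribution$attributions), "attributions.csv")
    jsonlite::write_json(list(ranking = res$attribution$ranking,
                              base_value = res$attribution$base_value,
                              scale = res$attribution$scale),
                         file.path(dir, "attribution_ranking.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths <- c(paths, file.path(dir, "attribution_ranking.json"))
  }
  if (!is.null(res$subgroups)) w(res$subgroups$cells, "subgroups.csv")

  unc <- res$cohort[res$cohort$censored == 0L, c("patient_id", "outcome")]
  ens <- merge(res$ensemble, unc, by = "patient_id")
  w(roc_coordinates(ens$ensemble, ens$outcome), "roc_ensemble.csv")

  summary <- list(
    seed = res$seed,
    best_family = res$best_family,
    cv_auc = as.list(res$cv_auc),
    evaluation = lapply(res$evaluation, function(e)
      list(auc = e$auc, ci = e$ci, n_pos = e$n_pos, n_neg = e$n_neg)),
    operating_points = lapply(res$operating_points, function(tier)
      lapply(tier, function(m) m[c("target", "threshold", "sensitivity",
                                   "specificity", "f1", "balanced_accuracy",
                                   "ppv", "npv")])),
    mcnemar = res$mcnemar,
    calibrators = lapply(res$calibrators, function(cl)
      list(slope = cl$slope, intercept = cl$intercept)),
    audits = lapply(res$audits, function(a) if (isTRUE(a)) TRUE else as.character(a))
  )
  jp <- file.path(dir, "evaluation.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, jp))
}
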