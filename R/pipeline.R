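#' Build phantom studies and imaging-branch inputs for a cohort
#'
#' For every imaging patient a phantom study is rendered whose lesion
#' geometry realizes the patient's latent lesion volume (the quantity that
#' drives outcome risk in the generator), then segmented with the
#' two-phase fuzzy c-means pipeline; volumetric features are assembled
#' into Dixon-ADC vectors, slice stacks are standardized at the requested
#' profile resolution, and the frozen trunk encoder is applied to produce
#' the collapsed subtraction statistics used for training.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param net_spec a [network_spec()] (its input shape sets the slice
#'   profile resolution).
#' @param seed integer seed.
#' @param grid_shape,grid_spacing phantom grid (desk-scale default
#'   48 x 24 x 16 voxels at 4 mm).
#' @param noise_sd phantom noise SD.
#' @param metadata_fields clinical metadata joined into the Dixon vector.
#' @return list (class `mpmri_inputs`): `patient_id`, `M` (collapsed
#'   subtraction statistics), `dixon` (raw Dixon vectors, NAs allowed),
#'   `features` (per-patient `volumetric_features`), `truth_volumes`
#'   (analytic lesion volumes, generator truth for recovery checks).
#' @export
build_mpmri_inputs <- function(cohort, net_spec, seed = 1L,
                               grid_shape = c(48L, 24L, 16L),
                               grid_spacing = c(4, 4, 4), noise_sd = 5,
                               metadata_fields = c("age", "bmi",
                                                   "tumor_size_mm", "tumor_grade")) {
  img <- cohort[cohort$has_imaging == 1L, ]
  net <- build_subtraction_net(net_spec)
  fov <- grid_shape * grid_spacing
  bsemi <- pmin(c(0.21, 0.40, 0.44) * fov, c(45, 42, 30))
  M <- NULL; dixon <- NULL; feats <- list(); truth_vol <- numeric(0)
  for (i in seq_len(nrow(img))) {
    pid <- img$patient_id[i]
    pseed <- derive_seed(seed, pid)
    les <- with_seed(pseed, {
      r <- (3 * exp(img$latent_log_volume[i]) / (4 * pi))^(1 / 3)
      f <- exp(stats::rnorm(3, 0, 0.15)); f <- f / prod(f)^(1 / 3)
      semi <- pmin(r * f, 0.5 * bsemi)
      side <- sample(c("left", "right"), 1)
      jit <- stats::rnorm(3, 0, 2)
      list(semi = semi, side = side, jit = jit)
    })
    sp <- phantom_spec(shape = grid_shape, spacing = grid_spacing,
                       lesions = list(), noise_sd = noise_sd, seed = pseed)
    center <- sp$breasts[[les$side]]$center + les$jit
    semi <- les$semi
    # shrink until the conservative containment test passes
    repeat {
      q <- sum(((abs(center - sp$breasts[[les$side]]$center) + semi) /
                  sp$breasts[[les$side]]$semiaxes)^2)
      if (q <= 1) break
      semi <- semi * 0.95
    }
    sp$lesions <- list(list(center = center, semiaxes = semi, side = les$side))
    ph <- generate_phantom(sp, patient_id = pid)
    seg <- suppressWarnings(segment_study(ph$study, seed = derive_seed(pseed, "seg")))
    vf <- extract_volumetric_features(seg$masks, ph$study)
    dv <- assemble_dixon_vector(vf, img[i, ], metadata_fields)
    stack <- prepare_slice_stack(ph$study, out_shape = net_spec$input_shape)
    Mi <- trunk_summary(trunk_maps(net, stack))
    M <- rbind(M, Mi); dixon <- rbind(dixon, dv)
    feats[[pid]] <- vf
    truth_vol[pid] <- ph$truth$analytic_volume
  }
  rownames(M) <- rownames(dixon) <- img$patient_id
  structure(list(patient_id = img$patient_id, M = M, dixon = dixon,
                 features = feats, truth_volumes = truth_vol,
                 net_spec = net_spec),
            class = "mpmri_inputs")
}

#' Run the full multimodal recurrence pipeline on synthetic data
#'
#' End to end: synthetic cohort, phantom imaging for the imaging subset,
#' side-model pseudo-labels, stratified cross-cohort folds, three seed
#' variations each of the clinical branch (family selected by
#' cross-validation AUC) and of the imaging branch, Platt calibration of
#' every variation on its out-of-fold scores, mean-of-available-scores
#' ensembling, the evaluation stack, the clinical attribution report, and
#' the integrity audits.
#'
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param n_clinical,n_imaging cohort sizes (defaults 800 / 200).
#' @param positive_rate,censoring_rate cohort rates (defaults 0.16 / 0.40).
#' @param image_shape slice profile resolution (desk-scale default 32 x 16).
#' @param n_variations model variations per modality (default 3).
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param sensitivity_targets operating points (default 0.87, 0.90, 0.93).
#' @param run_subgroups run the 432-cell subgroup scan.
#' @param run_explain compute the clinical attribution report.
#' @param ... further arguments to [build_mpmri_inputs()].
#' @return object of class `recurrence_pipeline`; see the methods vignette
#'   for the layout.
#' @export
run_recurrence_pipeline <- function(seed = 1L, n_clinical = 800L, n_imaging = 200L,
                                    positive_rate = 0.16, censoring_rate = 0.40,
                                    image_shape = c(32L, 16L), n_variations = 3L,
                                    n_boot = 1000L,
                                    sensitivity_targets = c(0.87, 0.90, 0.93),
                                    run_subgroups = FALSE, run_explain = TRUE, ...) {
  cohort <- generate_cohort(cohort_spec(n = n_clinical, n_imaging = n_imaging,
                                        positive_rate = positive_rate,
                                        censoring_rate = censoring_rate,
                                        seed = derive_seed(seed, "cohort")))
  pseudo <- pseudo_label(cohort, seed = derive_seed(seed, "pseudo"))
  plan <- make_folds(cohort, k = 5L, seed = derive_seed(seed, "folds"),
                     side_scores = pseudo)

  net_spec <- network_spec(input_shape = image_shape,
                           dixon_dim = 10L, seed = derive_seed(seed, "net"))
  inputs <- build_mpmri_inputs(cohort, net_spec, seed = derive_seed(seed, "imaging"), ...)

  # clinical branch: family selection on the first variation seed, then
  # further variations of the selected family
  var_seeds <- vapply(seq_len(n_variations),
                      function(i) derive_seed(seed, paste0("clinvar", i)), integer(1))
  sel <- train_select(cohort, plan, pseudo, seed = var_seeds[1])
  clinical_fits <- c(list(sel), lapply(var_seeds[-1], function(s)
    train_select(cohort, plan, pseudo, families = sel$best, seed = s)))

  mp_seeds <- vapply(seq_len(n_variations),
                     function(i) derive_seed(seed, paste0("mpvar", i)), integer(1))
  mpmri_fits <- lapply(mp_seeds, function(s)
    train_mpmri(inputs, cohort, plan, pseudo, net_spec, seed = s))

  # Platt calibration per variation, fitted on out-of-fold scores
  outcome_of <- function(ids) cohort$outcome[match(ids, cohort$patient_id)]
  score_table <- NULL; calibrators <- list()
  for (v in seq_len(n_variations)) {
    cs <- clinical_fits[[v]]$scores[[sel$best]]
    cal <- fit_platt(cs$score, outcome_of(cs$patient_id))
    calibrators[[paste0("clinical", v)]] <- cal
    score_table <- rbind(score_table,
                         data.frame(patient_id = cs$patient_id, modality = "clinical",
                                    variation = v, raw = cs$score,
                                    calibrated = apply_platt(cal, cs$score),
                                    stringsAsFactors = FALSE))
    ms <- mpmri_fits[[v]]$scores
    cal_m <- fit_platt(ms$score, outcome_of(ms$patient_id))
    calibrators[[paste0("mpmri", v)]] <- cal_m
    score_table <- rbind(score_table,
                         data.frame(patient_id = ms$patient_id, modality = "mpmri",
                                    variation = v, raw = ms$score,
                                    calibrated = apply_platt(cal_m, ms$score),
                                    stringsAsFactors = FALSE))
  }
  ensemble <- combine_scores(score_table)

  modality_mean <- function(mod) {
    st <- score_table[score_table$modality == mod, ]
    stats::aggregate(calibrated ~ patient_id, st, mean)
  }
  clin_mean <- modality_mean("clinical"); names(clin_mean)[2] <- "score"
  mp_mean <- modality_mean("mpmri"); names(mp_mean)[2] <- "score"

  unc <- cohort[cohort$censored == 0L, c("patient_id", "outcome", "has_imaging")]
  ens <- merge(ensemble, unc, by = "patient_id")
  img_ids <- unc$patient_id[unc$has_imaging == 1L]
  evalsets <- list(
    clinical_cohort = ens,
    imaging_cohort = ens[ens$patient_id %in% img_ids, ]
  )
  eval_on <- function(scores_df, col = "ensemble") {
    auc_ci(scores_df[[col]], scores_df$outcome, n_boot = n_boot,
           seed = derive_seed(seed, paste0("boot", col, nrow(scores_df))))
  }
  ic <- evalsets$imaging_cohort
  ic_clin <- merge(clin_mean, ic[, c("patient_id", "outcome")], by = "patient_id")
  ic_mp <- merge(mp_mean, ic[, c("patient_id", "outcome")], by = "patient_id")
  evaluation <- list(
    ensemble_clinical_cohort = eval_on(evalsets$clinical_cohort),
    ensemble_imaging_cohort = eval_on(evalsets$imaging_cohort),
    clinical_imaging_cohort = auc_ci(ic_clin$score, ic_clin$outcome, n_boot = n_boot,
                                     seed = derive_seed(seed, "bootclin")),
    mpmri_imaging_cohort = auc_ci(ic_mp$score, ic_mp$outcome, n_boot = n_boot,
                                  seed = derive_seed(seed, "bootmp"))
  )

  # operating points and McNemar comparisons on the imaging cohort
  models_ic <- list(mpmri = ic_mp[match(ic$patient_id, ic_mp$patient_id), "score"],
                    clinical = ic_clin[match(ic$patient_id, ic_clin$patient_id), "score"],
                    ensemble = ic$ensemble)
  op <- list(); mcn <- list()
  for (tg in sensitivity_targets) {
    key <- sprintf("%.2f", tg)
    op[[key]] <- lapply(models_ic, metrics_at_sensitivity,
                        labels = ic$outcome, target = tg)
    for (mod in c("mpmri", "clinical")) {
      pa <- as.integer(models_ic[[mod]] >= op[[key]][[mod]]$threshold)
      pb <- as.integer(models_ic$ensemble >= op[[key]]$ensemble$threshold)
      mcn[[paste(mod, "vs_ensemble", key, sep = "_")]] <-
        mcnemar_bonferroni(pa, pb, ic$outcome)
    }
  }

  attribution <- if (run_explain) {
    explain_clinical(cohort, pseudo, family = sel$best,
                     seed = derive_seed(seed, "explain"))
  }
  subgroups <- if (run_subgroups) {
    subgroup_scan(cohort, stats::setNames(ensemble[, c("patient_id", "ensemble")],
                                          c("patient_id", "score")),
                  n_boot = n_boot, seed = derive_seed(seed, "subgroups"))
  }

  audits <- list(
    evaluation_purity = audit_evaluation_purity(ens$patient_id, cohort),
    fold_correlation = audit_fold_correlation(plan, cohort),
    leakage_clinical = audit_no_leakage(sel),
    leakage_mpmri = audit_no_leakage(mpmri_fits[[1]])
  )
  for (v in seq_len(n_variations)) {
    st <- score_table[score_table$modality == "clinical" & score_table$variation == v, ]
    audits[[paste0("calibration_rank_clinical", v)]] <-
      audit_calibration_rank(st$raw, st$calibrated, outcome_of(st$patient_id))
    st <- score_table[score_table$modality == "mpmri" & score_table$variation == v, ]
    audits[[paste0("calibration_rank_mpmri", v)]] <-
      audit_calibration_rank(st$raw, st$calibrated, outcome_of(st$patient_id))
  }

  structure(list(seed = seed, cohort = cohort, plan = plan, pseudo = pseudo,
                 inputs = inputs, clinical = clinical_fits, mpmri = mpmri_fits,
                 best_family = sel$best, cv_auc = sel$cv_auc,
                 calibrators = calibrators, score_table = score_table,
                 ensemble = ensemble, evaluation = evaluation,
                 operating_points = op, mcnemar = mcn,
                 attribution = attribution, subgroups = subgroups,
                 audits = audits),
            class = "recurrence_pipeline")
}

#' @export
print.recurrence_pipeline <- function(x, ...) {
  cat("Multimodal recurrence pipeline (seed", x$seed, ")\n")
  cat(sprintf("  cohort: %d patients (%d imaging), %d uncensored\n",
              nrow(x$cohort), sum(x$cohort$has_imaging), sum(x$cohort$censored == 0)))
  cat("  selected clinical family:", x$best_family, "\n")
  e <- x$evaluation
  f <- function(a) sprintf("%.3f [%.3f, %.3f]", a$auc, a$ci[1], a$ci[2])
  cat("  AUC ensemble (clinical cohort):", f(e$ensemble_clinical_cohort), "\n")
  cat("  AUC ensemble (imaging cohort): ", f(e$ensemble_imaging_cohort), "\n")
  cat("  AUC clinical (imaging cohort): ", f(e$clinical_imaging_cohort), "\n")
  cat("  AUC mpMRI    (imaging cohort): ", f(e$mpmri_imaging_cohort), "\n")
  ok <- vapply(x$audits, isTRUE, logical(1))
  cat(sprintf("  audits: %d/%d passed\n", sum(ok), length(ok)))
  invisible(x)
}
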