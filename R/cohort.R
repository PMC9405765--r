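#' Names of the modelled clinical features
#'
#' The tabular feature set: patient characteristics (age, BMI),
#' immunohistochemistry (HER2, progesterone status, Ki67, mitotic index,
#' cancer subtype), tumor pathology (histological type, grade) and the
#' clinician's tumor-size estimate. Categorical codes: HER2 0/1;
#' histological type 1 NST, 2 lobular, 3 medullary, 4 other; progesterone
#' 0/1; cancer subtype 1 TNBC, 2 Luminal A, 3 Luminal B, 4 HER2+;
#' tumor grade 1-3 for I/II/III.
#' @return character vector of column names.
#' @export
clinical_feature_names <- function() {
  c("age", "bmi", "her2", "histological_type", "progesterone",
    "mitotic_index", "ki67", "tumor_grade", "cancer_subtype", "tumor_size_mm")
}

#' Specify a synthetic clinical cohort
#'
#' The cohort emulates a neoadjuvant-chemotherapy population: a binary
#' five-year recurrence outcome at a low positive rate, a censoring flag for
#' patients whose five-year outcome is unobserved, missing values in the
#' clinical features, and an imaging subset. Outcome risk follows a
#' logistic model on standardized scales whose default coefficients encode
#' the directions reported for this population: larger tumor volume raises
#' risk, higher BMI and older age lower it, and HER2-positive status is
#' protective (reflecting targeted anti-HER2 therapy).
#'
#' @param n cohort size (>= 20).
#' @param positive_rate target five-year recurrence rate.
#' @param censoring_rate target fraction of censored patients; censoring is
#'   drawn independently of the features.
#' @param n_imaging number of patients flagged as having mpMRI studies.
#' @param missingness named list of per-feature missingness rates.
#' @param risk_coefs named vector of logistic coefficients for
#'   `bmi`, `age` (per SD), `her2` (indicator) and `log_volume` (per SD of
#'   latent log lesion volume).
#' @param seed integer random seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 800L,
                        positive_rate = 0.16,
                        censoring_rate = 0.40,
                        n_imaging = min(200L, n),
                        missingness = NULL,
                        risk_coefs = c(bmi = -0.6, age = -0.6,
                                       her2 = -0.9, log_volume = 1.2),
                        seed = 1L) {
  n <- as.integer(n)
  if (n < 20L) stop("cohort size must be at least 20", call. = FALSE)
  rates <- c(positive_rate, censoring_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("positive and censoring rates must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(missingness)) {
    missingness <- list(age = 0, bmi = 0.05, her2 = 0.05, histological_type = 0.05,
                        progesterone = 0.05, mitotic_index = 0.15, ki67 = 0.15,
                        tumor_grade = 0.05, cancer_subtype = 0.10, tumor_size_mm = 0.05)
  }
  bad <- setdiff(names(missingness), clinical_feature_names())
  if (length(bad)) stop("unknown features in missingness: ", paste(bad, collapse = ", "))
  if (any(unlist(missingness) < 0) || any(unlist(missingness) > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("bmi", "age", "her2", "log_volume") %in% names(risk_coefs)))
  structure(list(n = n, positive_rate = positive_rate,
                 censoring_rate = censoring_rate,
                 n_imaging = as.integer(n_imaging),
                 missingness = missingness, risk_coefs = risk_coefs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic clinical cohort
#'
#' Draws patient-level clinical features with realistic dependence structure
#' (subtype drives HER2/progesterone/grade; grade drives Ki67 and mitotic
#' index; tumor size drives the latent lesion volume used by the phantom
#' generator), then draws the five-year recurrence outcome from the logistic
#' risk model of the spec, with the intercept solved so the expected
#' positive rate equals the target. Censoring and missingness are injected
#' afterwards, so the hidden `latent_log_volume` column stays a faithful
#' generator truth. Deterministic given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `patient_id`, the features of
#'   [clinical_feature_names()], `outcome` (NA for censored patients),
#'   `true_outcome`, `censored`, `has_imaging` and `latent_log_volume`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  co <- with_seed(spec$seed, {
    age <- pmin(pmax(stats::rnorm(n, 48, 10), 25), 80)
    bmi <- pmin(pmax(stats::rnorm(n, 25, 4.5), 16), 45)
    subtype <- sample.int(4L, n, replace = TRUE, prob = c(.15, .35, .30, .20))
    her2 <- ifelse(subtype == 4L, 1L, stats::rbinom(n, 1L, 0.08))
    prog <- stats::rbinom(n, 1L, ifelse(subtype %in% c(2L, 3L), 0.8, 0.2))
    gp <- rbind(c(.05, .35, .60), c(.35, .50, .15), c(.15, .50, .35), c(.10, .45, .45))
    grade <- vapply(subtype, function(s) sample.int(3L, 1L, prob = gp[s, ]), 1L)
    ki67 <- round(pmin(95, pmax(1, stats::rnorm(n, 10 + 12 * (grade - 1) + 5 * (subtype == 1L), 8))))
    mitot <- stats::rpois(n, 3 + 4 * (grade - 1))
    histo <- sample.int(4L, n, replace = TRUE, prob = c(.75, .15, .03, .07))
    size <- pmin(pmax(exp(stats::rnorm(n, log(28), 0.35)), 5), 120)
    log_vol <- log(4 / 3 * pi * (size / 2)^3) + stats::rnorm(n, 0, 0.35)

    zs <- function(x) (x - mean(x)) / stats::sd(x)
    b <- spec$risk_coefs
    lp <- b[["bmi"]] * zs(bmi) + b[["age"]] * zs(age) + b[["her2"]] * her2 +
      b[["log_volume"]] * zs(log_vol)
    b0 <- stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - spec$positive_rate,
                         interval = c(-30, 30))$root
    outcome <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))
    censored <- stats::rbinom(n, 1L, spec$censoring_rate)
    has_imaging <- integer(n)
    has_imaging[sample.int(n, spec$n_imaging)] <- 1L

    co <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age, bmi = bmi, her2 = her2, histological_type = histo,
      progesterone = prog, mitotic_index = mitot, ki67 = ki67,
      tumor_grade = grade, cancer_subtype = subtype, tumor_size_mm = size,
      true_outcome = outcome,
      outcome = ifelse(censored == 1L, NA_integer_, outcome),
      censored = censored, has_imaging = has_imaging,
      latent_log_volume = log_vol,
      stringsAsFactors = FALSE
    )
    for (f in names(spec$missingness)) {
      r <- spec$missingness[[f]]
      if (r > 0) co[[f]][stats::runif(n) < r] <- NA
    }
    co
  })
  n_pos_unc <- sum(co$outcome == 1L, na.rm = TRUE)
  if (n_pos_unc < 5L) {
    stop(sprintf(paste0("cohort has only %d uncensored positives; ",
                        "too few for stratified 5-fold cross-validation"), n_pos_unc),
         call. = FALSE)
  }
  co
}
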