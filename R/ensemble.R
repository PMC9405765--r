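#' Train seed variations of a model
#'
#' Runs a training routine `n` times, each with a different derived seed,
#' to produce model variations that differ only in their training seed —
#' the generalization device the ensemble averages over.
#'
#' @param train_fun function(seed) -> fitted model.
#' @param n number of variations (default 3).
#' @param base_seed integer base seed.
#' @return list with `models` (length n) and `seeds`.
#' @export
make_variations <- function(train_fun, n = 3L, base_seed = 1L) {
  seeds <- vapply(seq_len(n), function(i) derive_seed(base_seed, paste0("variation", i)),
                  integer(1))
  list(models = lapply(seeds, train_fun), seeds = seeds)
}

#' Platt calibration of classifier scores
#'
#' Fits the sigmoid `p = plogis(a * s + b)` by maximum likelihood against
#' Platt's prior-corrected targets `(n1 + 1)/(n1 + 2)` and `1/(n0 + 2)`
#' (which regularize the fit at the extremes). The map is strictly
#' monotone in the raw score; anti-correlated scores yield a negative
#' slope, i.e. calibration flips them.
#'
#' @param scores finite raw scores.
#' @param labels binary 0/1 labels (both classes required).
#' @return object of class `platt_calibrator` with `slope` and `intercept`.
#' @export
fit_platt <- function(scores, labels) {
  stopifnot(all(is.finite(scores)))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L) {
    stop("fit_platt: both classes must be present", call. = FALSE)
  }
  t <- ifelse(labels == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    p <- stats::plogis(par[1] * scores + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  gr <- function(par) {
    p <- stats::plogis(par[1] * scores + par[2])
    d <- p - t
    c(sum(d * scores), sum(d))
  }
  opt <- stats::optim(c(1, 0), nll, gr, method = "BFGS",
                      control = list(maxit = 200))
  structure(list(slope = opt$par[1], intercept = opt$par[2],
                 converged = opt$convergence == 0),
            class = "platt_calibrator")
}

#' @rdname fit_platt
#' @param calibrator a fitted `platt_calibrator`.
#' @param newscores scores to calibrate.
#' @export
apply_platt <- function(calibrator, newscores) {
  stats::plogis(calibrator$slope * newscores + calibrator$intercept)
}

#' Combine calibrated scores by the mean of available scores
#'
#' The ensemble score of a patient is the arithmetic mean of all available
#' calibrated scores (up to six: three clinical variations plus three
#' imaging variations); patients without imaging are averaged over their
#' clinical scores only. A patient with no score at all is an error.
#'
#' @param score_table data.frame with `patient_id`, `modality`,
#'   `variation`, `calibrated` (NAs allowed and ignored).
#' @return data.frame (`patient_id`, `n_scores`, `ensemble`).
#' @export
combine_scores <- function(score_table) {
  stopifnot(all(c("patient_id", "calibrated") %in% names(score_table)))
  sp <- split(score_table$calibrated, score_table$patient_id)
  n_scores <- vapply(sp, function(s) sum(!is.na(s)), integer(1))
  if (any(n_scores == 0L)) {
    stop("combine_scores: patient(s) with zero available scores: ",
         paste(utils::head(names(sp)[n_scores == 0L]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(patient_id = names(sp),
             n_scores = n_scores,
             ensemble = vapply(sp, function(s) mean(s, na.rm = TRUE), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
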