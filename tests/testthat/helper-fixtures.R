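# Shared fixtures, all generated in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digital sphere mask: radius in mm, isotropic spacing, centered grid
digital_sphere <- function(radius, spacing = 1, margin = 3L) {
  n <- as.integer(ceiling(2 * radius / spacing)) + 2L * margin
  cx <- (seq_len(n) - 0.5) * spacing
  ctr <- mean(cx)
  q <- outer(outer((cx - ctr)^2, (cx - ctr)^2, "+"), (cx - ctr)^2, "+")
  array(q <= radius^2, dim = c(n, n, n))
}

# independent BFS flood-fill labelling oracle (26-connectivity)
floodfill_label <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, dm)
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] + (nb[ok, 3] - 1L) * dm[1] * dm[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      queue <- c(queue, lin)
    }
  }
  lab
}

# brute-force AUC oracle: exhaustive pairwise concordance
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# exhaustive operating-point oracle: enumerate every distinct threshold
op_oracle <- function(scores, labels, target) {
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred & labels); fn <- sum(!pred & labels)
    tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
    sens <- tp / (tp + fn)
    if (sens >= target) { best <- list(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
                                       sens = sens, spec = tn / (tn + fp)); break }
  }
  if (is.null(best)) return(NULL)
  ppv <- if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_
  best$ppv <- ppv
  best$npv <- if (best$tn + best$fn > 0) best$tn / (best$tn + best$fn) else NA_real_
  best$f1 <- if (is.na(ppv) || ppv + best$sens == 0) 0 else
    2 * ppv * best$sens / (ppv + best$sens)
  best$bacc <- (best$sens + best$spec) / 2
  best
}

# exact two-sided McNemar oracle by binomial tail summation
mcnemar_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(sapply(0:k, function(i) choose(n, i) * 0.5^n)))
}

# hand-built cohort with exact class counts (cv/clinical module tests)
make_cv_cohort <- function(n_pos = 50L, n_neg = 250L, n_cens = 0L, seed = 1L) {
  set.seed(seed)
  n <- n_pos + n_neg + n_cens
  out <- c(rep(1L, n_pos), rep(0L, n_neg), rep(NA_integer_, n_cens))
  data.frame(patient_id = sprintf("C%04d", seq_len(n)),
             age = rnorm(n, 50, 8), bmi = rnorm(n, 25, 4),
             her2 = rbinom(n, 1, .2), histological_type = sample(1:4, n, TRUE),
             progesterone = rbinom(n, 1, .5), mitotic_index = rpois(n, 5),
             ki67 = runif(n, 1, 60), tumor_grade = sample(1:3, n, TRUE),
             cancer_subtype = sample(1:4, n, TRUE), tumor_size_mm = runif(n, 10, 60),
             outcome = out,
             true_outcome = ifelse(is.na(out), rbinom(n, 1, .16), out),
             censored = as.integer(is.na(out)),
             has_imaging = rbinom(n, 1, .3), stringsAsFactors = FALSE)
}

# session-cached full pipeline runs (shared between module tests and the
# acceptance suite so the expensive runs happen once)
.pipeline_cache <- new.env(parent = emptyenv())
get_pipeline <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_recurrence_pipeline(seed = seed)
  }
  .pipeline_cache[[key]]
}

# small volume-driven imaging cohort + inputs, cached (mpmri module tests)
.inputs_cache <- new.env(parent = emptyenv())
get_volume_driven_inputs <- function(seed = 401L, n = 200L) {
  key <- paste0("vd", seed, "_", n)
  if (is.null(.inputs_cache[[key]])) {
    co <- generate_cohort(cohort_spec(
      n = n, n_imaging = n, positive_rate = 0.16, censoring_rate = 0,
      risk_coefs = c(bmi = 0, age = 0, her2 = 0, log_volume = 1.5),
      seed = seed))
    ns <- network_spec(input_shape = c(32L, 16L), dixon_dim = 10L,
                       seed = seed)
    iv <- build_mpmri_inputs(co, ns, seed = seed + 1L)
    .inputs_cache[[key]] <- list(cohort = co, spec = ns, inputs = iv)
  }
  .inputs_cache[[key]]
}
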