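## Dense-layer machinery for the trainable stages of the imaging branch
## (3D conv + Dixon head + fusion head) and for gradient-checked training.

dense_init <- function(sizes, seed) {
  # sizes: vector of layer widths including input dim
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(i) {
      fin <- sizes[i]
      list(W = matrix(stats::rnorm(fin * sizes[i + 1L], 0, sqrt(2 / fin)),
                      fin, sizes[i + 1L]),
           b = numeric(sizes[i + 1L]))
    })
  })
}

dense_forward <- function(x, params, acts) {
  cache <- list(a = list(x))
  for (i in seq_along(params)) {
    z <- sweep(x %*% params[[i]]$W, 2, params[[i]]$b, "+")
    x <- if (acts[i] == "relu") relu(z) else z
    cache$z[[i]] <- z
    cache$a[[i + 1L]] <- x
  }
  list(out = x, cache = cache)
}

dense_backward <- function(dout, params, acts, cache) {
  grads <- vector("list", length(params))
  for (i in rev(seq_along(params))) {
    if (acts[i] == "relu") dout <- dout * (cache$z[[i]] > 0)
    grads[[i]] <- list(W = crossprod(cache$a[[i]], dout),
                       b = colSums(dout))
    dout <- dout %*% t(params[[i]]$W)
  }
  list(grads = grads, dinput = dout)
}

adam_state <- function(theta) {
  if (is.list(theta) && !is.matrix(theta)) return(lapply(theta, adam_state))
  list(m = 0 * theta, v = 0 * theta)
}

# flat parameter list utilities: theta is a nested list of numeric arrays
flat_apply <- function(theta, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8, t = 1) {
  upd <- function(th, gr, st) {
    if (is.list(th) && !is.matrix(th)) {
      out <- mapply(upd, th, gr, st, SIMPLIFY = FALSE)
      return(list(theta = lapply(out, `[[`, "theta"),
                  state = lapply(out, `[[`, "state")))
    }
    st$m <- b1 * st$m + (1 - b1) * gr
    st$v <- b2 * st$v + (1 - b2) * gr^2
    mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
    list(theta = th - lr * mh / (sqrt(vh) + eps), state = st)
  }
  upd(theta, grads, state)
}

## Forward/backward through the trainable stages. M: collapsed subtraction
## statistics (n x 3*256); D: preprocessed dixon vectors (n x q).
mpmri_theta_init <- function(spec, seed) {
  cin <- spec$trunk_widths[length(spec$trunk_widths)]
  nf <- spec$subtraction_features
  with_seed(seed, {
    list(
      W3 = matrix(stats::rnorm(3 * cin * nf, 0, sqrt(1 / (3 * cin))), 3 * cin, nf),
      b3 = numeric(nf),
      dixon = dense_init(c(spec$dixon_dim, spec$dixon_widths),
                         derive_seed(seed, "dixon")),
      fusion = dense_init(c(nf + spec$dixon_widths[length(spec$dixon_widths)],
                            spec$fusion_widths), derive_seed(seed, "fusion"))
    )
  })
}

mpmri_forward <- function(theta, M, D, spec) {
  nd <- length(spec$dixon_widths)
  g <- sweep(M %*% theta$W3, 2, theta$b3, "+")
  dh <- dense_forward(D, theta$dixon, rep("relu", nd))
  z <- cbind(g, dh$out)
  fw <- dense_forward(z, theta$fusion,
                      c(rep("relu", length(spec$fusion_widths) - 1L), "identity"))
  p <- stats::plogis(fw$out[, 1])
  list(p = p, logits = fw$out[, 1], g = g, dh = dh, fw = fw, z = z)
}

mpmri_backward <- function(fwd, theta, M, D, y, w, spec) {
  n <- length(y)
  dlogit <- matrix(w * (fwd$p - y) / sum(w), n, 1)
  bf <- dense_backward(dlogit, theta$fusion,
                       c(rep("relu", length(spec$fusion_widths) - 1L), "identity"),
                       fwd$fw$cache)
  nf <- spec$subtraction_features
  dg <- bf$dinput[, seq_len(nf), drop = FALSE]
  dhd <- bf$dinput[, -seq_len(nf), drop = FALSE]
  bd <- dense_backward(dhd, theta$dixon, rep("relu", length(spec$dixon_widths)),
                       fwd$dh$cache)
  list(W3 = crossprod(M, dg), b3 = colSums(dg),
       dixon = bd$grads, fusion = bf$grads)
}

weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

# Train the trainable stages on one fold. Returns theta, training history
# and the epoch selected by early stopping.
train_mpmri_fold <- function(M, D, y, spec, seed, val = NULL) {
  w <- if (spec$class_weighted) class_weights(y)$weights else rep(1, length(y))
  theta <- mpmri_theta_init(spec, seed)
  state <- adam_state(theta)
  n <- length(y)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  t_step <- 0
  for (epoch in seq_len(spec$epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)), sample.int(n))
    for (start in seq(1L, n, by = spec$batch_size)) {
      bi <- ord[start:min(start + spec$batch_size - 1L, n)]
      fwd <- mpmri_forward(theta, M[bi, , drop = FALSE], D[bi, , drop = FALSE], spec)
      grads <- mpmri_backward(fwd, theta, M[bi, , drop = FALSE],
                              D[bi, , drop = FALSE], y[bi], w[bi], spec)
      t_step <- t_step + 1
      up <- flat_apply(theta, grads, state, spec$lr, t = t_step)
      theta <- up$theta; state <- up$state
    }
    tr <- mpmri_forward(theta, M, D, spec)
    tl <- weighted_bce(tr$p, y, w)
    vl <- NA_real_
    if (!is.null(val)) {
      vp <- mpmri_forward(theta, val$M, val$D, spec)$p
      vl <- weighted_bce(vp, val$y, rep(1, length(val$y)))
      if (vl < best$loss - 1e-6) best <- list(loss = vl, theta = theta, epoch = epoch)
      if (epoch - best$epoch >= spec$patience) {
        history <- rbind(history, data.frame(epoch = epoch, train_loss = tl, val_loss = vl))
        break
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl, val_loss = vl))
  }
  if (is.null(val) || !is.finite(best$loss)) best <- list(loss = NA_real_, theta = theta,
                                                          epoch = nrow(history))
  list(theta = best$theta, history = history, stopped_epoch = best$epoch)
}

#' Train the imaging branch with censoring-aware cross-validation
#'
#' Five fold-models are trained on the collapsed subtraction statistics and
#' Dixon-ADC vectors: in every iteration the validation fold is held out,
#' censored patients are kept in the training folds with their side-model
#' pseudo-labels, and out-of-fold scores are produced only for uncensored
#' validation patients. Dixon vectors are imputed and scaled with
#' training-fold statistics only.
#'
#' @param inputs list with `patient_id`, `M` (n x 768 collapsed subtraction
#'   statistics), `dixon` (n x q raw Dixon vectors, NAs allowed); see
#'   [build_mpmri_inputs()].
#' @param cohort cohort data.frame (provides outcome and censoring).
#' @param plan a [make_folds()] plan.
#' @param pseudo a [pseudo_label()] result (may have zero rows).
#' @param spec a [network_spec()] with `dixon_dim = ncol(dixon)`.
#' @param seed training seed (the "variation" seed of the ensemble stage).
#' @return object of class `mpmri_fit`: fold models with their
#'   preprocessing statistics and training-ID audit trail, the out-of-fold
#'   `scores` data.frame, and per-fold histories.
#' @export
train_mpmri <- function(inputs, cohort, plan, pseudo, spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), ncol(inputs$dixon) == spec$dixon_dim)
  ids <- inputs$patient_id
  info <- merge(data.frame(patient_id = ids, row = seq_along(ids)),
                cohort[, c("patient_id", "outcome", "censored")], by = "patient_id")
  info <- info[order(info$row), ]
  fold <- plan$fold[match(ids, plan$patient_id)]
  if (any(is.na(fold))) stop("train_mpmri: imaging patient missing from fold plan")
  lab <- info$outcome
  if (nrow(pseudo)) {
    pl <- pseudo$pseudo_label[match(ids, pseudo$patient_id)]
    lab[info$censored == 1L] <- pl[info$censored == 1L]
  }
  if (any(is.na(lab) & info$censored == 1L)) {
    stop("train_mpmri: censored patients lack pseudo-labels")
  }

  folds <- sort(unique(fold))
  models <- list(); oof <- NULL; histories <- list()
  for (f in folds) {
    tr_rows <- which(fold != f)
    va_rows <- which(fold == f & info$censored == 0L)
    imp <- impute_by_train_means(inputs$dixon, tr_rows)
    sc <- fit_minmax(imp$x[tr_rows, , drop = FALSE])
    Dall <- apply_minmax(sc, imp$x)
    fit <- train_mpmri_fold(inputs$M[tr_rows, , drop = FALSE],
                            Dall[tr_rows, , drop = FALSE], lab[tr_rows],
                            spec, derive_seed(seed, paste0("fold", f)),
                            val = list(M = inputs$M[va_rows, , drop = FALSE],
                                       D = Dall[va_rows, , drop = FALSE],
                                       y = lab[va_rows]))
    models[[as.character(f)]] <- list(theta = fit$theta, dixon_means = imp$means,
                                      minmax = sc, fold = f,
                                      train_ids = ids[tr_rows])
    histories[[as.character(f)]] <- fit$history
    if (length(va_rows)) {
      p <- mpmri_forward(fit$theta, inputs$M[va_rows, , drop = FALSE],
                         Dall[va_rows, , drop = FALSE], spec)$p
      oof <- rbind(oof, data.frame(patient_id = ids[va_rows], fold = f,
                                   score = p, stringsAsFactors = FALSE))
    }
  }
  structure(list(models = models, scores = oof, spec = spec, seed = seed,
                 histories = histories, modality = "mpmri"),
            class = "mpmri_fit")
}

#' Score patients with the trained imaging branch (holdout rule)
#'
#' The holdout score of a patient is the arithmetic mean of the scores of
#' the five fold-models.
#'
#' @param fit an `mpmri_fit`.
#' @param inputs as in [train_mpmri()].
#' @return data.frame with `patient_id` and `score`.
#' @export
predict_mpmri_holdout <- function(fit, inputs) {
  scores <- sapply(fit$models, function(m) {
    x <- inputs$dixon
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- m$dixon_means[j]
    D <- apply_minmax(m$minmax, x)
    mpmri_forward(m$theta, inputs$M, D, fit$spec)$p
  })
  data.frame(patient_id = inputs$patient_id,
             score = rowMeans(matrix(scores, nrow = length(inputs$patient_id))),
             stringsAsFactors = FALSE)
}
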