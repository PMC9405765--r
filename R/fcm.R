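#' Fuzzy c-means clustering
#'
#' Classical fuzzy c-means: minimize the fuzzified within-cluster sum of
#' squares `sum_i sum_j u_ij^m ||x_i - c_j||^2` by alternating membership
#' and center updates. Memberships are row-normalized at every step and the
#' objective is non-increasing across iterations; convergence is declared
#' when the largest center shift drops below `tol`. Centers are initialized
#' by quantile spacing along the first principal coordinate, so a run is
#' deterministic given the seed (the seed is kept for provenance and for
#' any downstream tie-breaking).
#'
#' @param points numeric matrix (n points x d features) or vector.
#' @param k number of clusters (>= 1).
#' @param m fuzziness exponent (> 1).
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap.
#' @param seed integer seed recorded in the result.
#' @param init_probs quantile positions (length k) for center
#'   initialization along the dominant direction; the default spans the
#'   1st-99th percentile.
#' @return object of class `fcm_result` with `centers` (k x d),
#'   `membership` (n x k), `iterations`, `objective` (per-iteration trace;
#'   last entry is the final value) and `hard` (argmax labels, ties to the
#'   lower cluster index).
#' @export
fcm <- function(points, k, m = 2, tol = 1e-4, max_iter = 300L, seed = 1L,
                init_probs = NULL) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("fcm: input contains non-finite values", call. = FALSE)
  if (k < 1L) stop("fcm: k must be >= 1", call. = FALSE)
  if (m <= 1) stop("fcm: fuzziness m must be > 1", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  if (nrow(unique(x)) < k) {
    stop("fcm: k exceeds the number of distinct points", call. = FALSE)
  }

  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L, d)
    obj <- sum(sweep(x, 2, ctr[1L, ])^2)
    return(structure(list(centers = ctr, membership = matrix(1, n, 1L),
                          iterations = 0L, objective = obj,
                          hard = rep(1L, n), seed = as.integer(seed)),
                     class = "fcm_result"))
  }

  # quantile-spaced init along the dominant direction: robust, deterministic
  proj <- if (d == 1L) x[, 1L] else {
    ctrd <- sweep(x, 2, colMeans(x))
    sv <- La.svd(crossprod(ctrd) / n, nu = 0, nv = ncol(x))
    drop(ctrd %*% sv$vt[1L, ])
  }
  # spacing spans the 1st-99th percentile so small extreme clusters (e.g. a
  # bright lesion occupying a few percent of the voxels) attract a center
  if (is.null(init_probs)) init_probs <- seq(0.01, 0.99, length.out = k)
  stopifnot(length(init_probs) == k)
  qs <- stats::quantile(proj, probs = init_probs, names = FALSE, type = 7)
  centers <- t(vapply(qs, function(q) x[which.min(abs(proj - q)), ], numeric(d)))
  centers <- matrix(centers, k, d)

  sqdist <- function(ctr) {
    # n x k matrix of squared Euclidean distances
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(ctr) +
      outer(rep(1, n), rowSums(ctr^2))
    pmax(d2, 0)
  }
  objective <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(centers)
    zero <- d2 < 1e-12
    # membership update: u_ij = 1 / sum_l (d_ij / d_il)^(1/(m-1))
    w <- (1 / (d2 + 1e-300))^(1 / (m - 1))
    u <- w / rowSums(w)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- 0
      u[cbind(which(hit), max.col(-d2[hit, , drop = FALSE], ties.method = "first"))] <- 1
    }
    um <- u^m
    objective <- c(objective, sum(um * d2))
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  hard <- max.col(u, ties.method = "first")
  structure(list(centers = centers, membership = u, iterations = it,
                 objective = objective, hard = hard, seed = as.integer(seed)),
            class = "fcm_result")
}
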