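small_spec <- function(seed = 1L, ...) {
  network_spec(input_shape = c(32L, 16L), dixon_dim = 4L, seed = seed, ...)
}

rand_stack <- function(seed = 1, shape = c(32L, 16L)) {
  set.seed(seed)
  structure(list(slices = array(runif(prod(shape) * 7), c(shape, 7L)),
                 tumor_side = "left", flipped = FALSE),
            class = "slice_stack")
}

test_that("architecture widths match the fixed design exactly", {
  arch <- network_architecture(small_spec())
  blocks <- arch[grepl("res_block", arch$stage), ]
  expect_equal(blocks$width, c(32L, 64L, 64L, 128L, 128L, 256L, 256L))
  expect_equal(nrow(blocks), 7L)
  expect_equal(arch$width[grepl("dixon_fc", arch$stage)], c(16L, 16L, 16L, 32L, 32L))
  expect_equal(arch$width[grepl("fusion_fc", arch$stage)], c(64L, 32L, 1L))
  expect_equal(arch$width[arch$stage == "global_avg_pool"], 32L)
  # production input geometry is the default
  expect_equal(network_spec(dixon_dim = 4L)$input_shape, c(512L, 256L))
})

test_that("the subtraction component outputs exactly 32 features", {
  net <- build_subtraction_net(small_spec())
  f <- subtraction_features(net, rand_stack(1))
  expect_length(f, 32L)
  expect_true(all(is.finite(f)))
})

test_that("inputs of the wrong shape raise a shape error", {
  net <- build_subtraction_net(small_spec())
  bad <- rand_stack(1, shape = c(16L, 8L))
  expect_error(subtraction_features(net, bad), "must be 32 x 16 x 7")
  expect_error(subtraction_features(net, array(0, c(32, 16, 5))), "shape|must be")
})

test_that("slice order matters only through the 3D convolution", {
  spec <- small_spec(seed = 3)
  st <- rand_stack(3)
  perm <- c(4, 1, 6, 2, 7, 3, 5)
  st_perm <- st; st_perm$slices <- st$slices[, , perm]
  # depth-1 kernel: global pooling makes slice order irrelevant
  net1 <- build_subtraction_net(spec, conv3d_kernel_depth = 1L)
  expect_equal(subtraction_features(net1, st), subtraction_features(net1, st_perm),
               tolerance = 1e-10)
  # depth-3 kernel: order is visible
  net3 <- build_subtraction_net(spec, conv3d_kernel_depth = 3L)
  expect_gt(max(abs(subtraction_features(net3, st) -
                      subtraction_features(net3, st_perm))), 1e-8)
})

test_that("identical calls on a constant stack are deterministic", {
  net <- build_subtraction_net(small_spec(seed = 4))
  zs <- rand_stack(1); zs$slices[] <- 0
  expect_identical(subtraction_features(net, zs), subtraction_features(net, zs))
})

test_that("collapsed subtraction statistics reproduce the explicit branch", {
  net <- build_subtraction_net(small_spec(seed = 5))
  st <- rand_stack(5)
  explicit <- subtraction_features(net, st)
  M <- trunk_summary(trunk_maps(net, st))
  collapsed <- as.vector(M %*% matrix(net$w3, 3 * 256, 32)) + net$b3
  expect_equal(explicit, collapsed, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- small_spec(seed = 6)
  set.seed(6)
  n <- 5
  M <- matrix(rnorm(n * 768, 0, 0.3), n, 768)
  D <- matrix(runif(n * 4), n, 4)
  y <- c(1, 0, 1, 0, 1); w <- rep(1, n)
  theta <- mmrecur:::mpmri_theta_init(spec, 1L)
  fwd <- mmrecur:::mpmri_forward(theta, M, D, spec)
  gr <- mmrecur:::mpmri_backward(fwd, theta, M, D, y, w, spec)
  lossfn <- function(th) {
    p <- mmrecur:::mpmri_forward(th, M, D, spec)$p
    mmrecur:::weighted_bce(p, y, w)
  }
  eps <- 1e-5
  # spot-check entries across all parameter groups
  checks <- list(
    list(get = function(th) th$W3[5, 2], set = function(th, v) { th$W3[5, 2] <- v; th },
         g = gr$W3[5, 2]),
    list(get = function(th) th$b3[3], set = function(th, v) { th$b3[3] <- v; th },
         g = gr$b3[3]),
    list(get = function(th) th$dixon[[2]]$W[1, 4],
         set = function(th, v) { th$dixon[[2]]$W[1, 4] <- v; th },
         g = gr$dixon[[2]]$W[1, 4]),
    list(get = function(th) th$fusion[[3]]$W[10, 1],
         set = function(th, v) { th$fusion[[3]]$W[10, 1] <- v; th },
         g = gr$fusion[[3]]$W[10, 1]),
    list(get = function(th) th$fusion[[1]]$b[7],
         set = function(th, v) { th$fusion[[1]]$b[7] <- v; th },
         g = gr$fusion[[1]]$b[7])
  )
  for (ck in checks) {
    v0 <- ck$get(theta)
    num <- (lossfn(ck$set(theta, v0 + eps)) - lossfn(ck$set(theta, v0 - eps))) / (2 * eps)
    expect_equal(ck$g, num, tolerance = 1e-4)
  }
})

test_that("imaging training recovers a volume-driven outcome out of fold", {
  fx <- get_volume_driven_inputs()
  plan <- make_folds(fx$cohort, seed = 31)
  pseudo <- pseudo_label(fx$cohort, seed = 31)
  fit <- train_mpmri(fx$inputs, fx$cohort, plan, pseudo, fx$spec, seed = 31)
  m <- merge(fit$scores, fx$cohort[, c("patient_id", "outcome")])
  expect_gte(auc(m$score, m$outcome), 0.75)
  # training loss decreases on every fold
  for (h in fit$histories) {
    expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
  }
})

test_that("shuffled labels give chance-level out-of-fold AUC", {
  fx <- get_volume_driven_inputs()
  spec <- fx$spec; spec$epochs <- 15L
  aucs <- vapply(1:10, function(i) {
    co <- fx$cohort
    set.seed(100 + i)
    sh <- sample(nrow(co))
    co$outcome <- co$outcome[sh]; co$true_outcome <- co$true_outcome[sh]
    plan <- make_folds(co, seed = i)
    fit <- train_mpmri(fx$inputs, co, plan, pseudo_label(co, seed = i), spec, seed = i)
    m <- merge(fit$scores, co[, c("patient_id", "outcome")])
    auc(m$score, m$outcome)
  }, numeric(1))
  expect_gte(mean(aucs), 0.42); expect_lte(mean(aucs), 0.58)
  expect_gte(sum(aucs >= 0.4 & aucs <= 0.6), 8)
})

test_that("holdout scores equal the mean of the five fold-model scores", {
  fx <- get_volume_driven_inputs()
  plan <- make_folds(fx$cohort, seed = 32)
  fit <- train_mpmri(fx$inputs, fx$cohort, plan, pseudo_label(fx$cohort, seed = 32),
                     fx$spec, seed = 32)
  hold <- predict_mpmri_holdout(fit, fx$inputs)
  per_model <- sapply(fit$models, function(m) {
    x <- fx$inputs$dixon
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- m$dixon_means[j]
    mmrecur:::mpmri_forward(m$theta, fx$inputs$M, apply_minmax(m$minmax, x),
                            fit$spec)$p
  })
  expect_equal(hold$score, unname(rowMeans(per_model)), tolerance = 1e-12)
})

test_that("no out-of-fold score comes from a model trained on that patient", {
  fx <- get_volume_driven_inputs()
  plan <- make_folds(fx$cohort, seed = 33)
  fit <- train_mpmri(fx$inputs, fx$cohort, plan, pseudo_label(fx$cohort, seed = 33),
                     fx$spec, seed = 33)
  expect_true(isTRUE(audit_no_leakage(fit)))
})
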