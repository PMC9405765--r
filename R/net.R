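#' Imaging network specification
#'
#' The fixed architecture of the imaging branch: a shared-weight 2D
#' residual trunk applied to each of the 7 subtraction slices (7 residual
#' blocks, filter widths 32, 64, 64, 128, 128, 256, 256, stride-2
#' downsampling where the width increases), per-slice feature maps stacked
#' along a depth axis, one 3D convolution (depth-3 kernel over the slice
#' axis, 32 output channels), global average pooling to 32 subtraction
#' features; a dense Dixon head with layer widths 16, 16, 16, 32, 32; and
#' a fusion head with widths 64, 32, 1 ending in a sigmoid. The block and
#' layer widths are part of the design and are not parameters; the spec
#' only exposes the input geometry and training hyperparameters.
#'
#' @param input_shape slice size fed to the trunk; the production size is
#'   512 x 256, reduced desk-scale profiles keep the 2:1 aspect.
#' @param dixon_dim length of the assembled Dixon-ADC input vector.
#' @param seed integer seed for the frozen trunk encoder initialization.
#' @param lr,epochs,batch_size,patience,class_weighted training
#'   hyperparameters (Adam learning rate, epoch cap, minibatch size, early
#'   stopping patience on fold-validation loss, class-weighted binary
#'   cross-entropy).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(512L, 256L), dixon_dim = 10L,
                         seed = 1L, lr = 3e-3, epochs = 200L, batch_size = 32L,
                         patience = 30L, class_weighted = TRUE) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 2L, all(input_shape >= 8L),
            input_shape[1] %% 8L == 0L, input_shape[2] %% 8L == 0L)
  structure(list(
    input_shape = input_shape,
    n_slices = 7L,
    trunk_widths = c(32L, 64L, 64L, 128L, 128L, 256L, 256L),
    subtraction_features = 32L,
    conv3d_depth = 3L,
    dixon_widths = c(16L, 16L, 16L, 32L, 32L),
    fusion_widths = c(64L, 32L, 1L),
    dixon_dim = as.integer(dixon_dim),
    seed = as.integer(seed),
    lr = lr, epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    patience = as.integer(patience), class_weighted = class_weighted
  ), class = "network_spec")
}

#' Architecture table for introspection
#'
#' One row per stage with its output width and stride; used to assert the
#' fixed widths of the design.
#' @param spec a [network_spec()].
#' @return data.frame with `stage`, `width`, `stride`.
#' @export
network_architecture <- function(spec) {
  w <- spec$trunk_widths
  prev <- c(32L, w[-length(w)])
  strides <- ifelse(w > prev, 2L, 1L)
  rbind(
    data.frame(stage = "stem_conv", width = 32L, stride = 1L),
    data.frame(stage = sprintf("res_block_%d", seq_along(w)), width = w, stride = strides),
    data.frame(stage = "conv3d", width = spec$subtraction_features, stride = 1L),
    data.frame(stage = "global_avg_pool", width = spec$subtraction_features, stride = 1L),
    data.frame(stage = sprintf("dixon_fc_%d", seq_along(spec$dixon_widths)),
               width = spec$dixon_widths, stride = 1L),
    data.frame(stage = sprintf("fusion_fc_%d", seq_along(spec$fusion_widths)),
               width = spec$fusion_widths, stride = 1L)
  )
}

## ---- primitive layers (N, H, W, C arrays, column-major) ----

relu <- function(x) pmax(x, 0)

# 2D convolution with 'same' padding via shift-and-matmul: one BLAS matmul
# per kernel tap instead of an explicit im2col buffer.
conv2d <- function(x, w, b = NULL, stride = 1L) {
  dm <- dim(x); n <- dm[1]; h <- dm[2]; wd <- dm[3]; cin <- dm[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ho <- as.integer(ceiling(h / stride)); wo <- as.integer(ceiling(wd / stride))
  ph <- max(0L, (ho - 1L) * stride + kh - h); pw <- max(0L, (wo - 1L) * stride + kw - wd)
  ph0 <- ph %/% 2L; pw0 <- pw %/% 2L
  xp <- array(0, c(n, h + ph, wd + pw, cin))
  xp[, ph0 + seq_len(h), pw0 + seq_len(wd), ] <- x
  wm <- matrix(w, kh * kw * cin, cout)
  out <- matrix(0, n * ho * wo, cout)
  for (a in seq_len(kh)) for (bb in seq_len(kw)) {
    rows <- a + stride * (seq_len(ho) - 1L)
    cols <- bb + stride * (seq_len(wo) - 1L)
    sl <- xp[, rows, cols, , drop = FALSE]
    dim(sl) <- c(n * ho * wo, cin)
    tap <- ((a - 1L) + (bb - 1L) * kh) * cin + seq_len(cin)
    out <- out + sl %*% wm[tap, , drop = FALSE]
  }
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  dim(out) <- c(n, ho, wo, cout)
  out
}

# Per-sample, per-channel normalization (instance normalization without
# affine parameters). Deterministic for a frozen encoder: no batch or
# running statistics.
instance_norm <- function(x, eps = 1e-5) {
  dm <- dim(x); n <- dm[1]; hw <- dm[2] * dm[3]; cc <- dm[4]
  xt <- aperm(x, c(2, 3, 1, 4)); dim(xt) <- c(hw, n * cc)
  m <- colMeans(xt)
  v <- colMeans(xt^2) - m^2
  xt <- sweep(xt, 2, m, "-")
  xt <- sweep(xt, 2, sqrt(pmax(v, 0) + eps), "/")
  dim(xt) <- c(dm[2], dm[3], n, cc)
  aperm(xt, c(3, 1, 2, 4))
}

he_weights <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Frozen random-feature residual trunk: the full architecture, initialized
# once from the spec seed and never updated (see the methods vignette for
# the design rationale).
trunk_init <- function(spec) {
  with_seed(spec$seed, {
    widths <- spec$trunk_widths
    prev <- 32L
    layers <- list(stem = list(w = he_weights(3, 3, 1, 32)))
    blocks <- list()
    for (i in seq_along(widths)) {
      w <- widths[i]
      stride <- if (w > prev) 2L else 1L
      bl <- list(stride = stride,
                 conv1 = he_weights(3, 3, prev, w),
                 conv2 = he_weights(3, 3, w, w),
                 shortcut = if (stride > 1L || w != prev) he_weights(1, 1, prev, w))
      blocks[[i]] <- bl
      prev <- w
    }
    list(stem = layers$stem, blocks = blocks)
  })
}

trunk_forward <- function(trunk, x) {
  y <- relu(instance_norm(conv2d(x, trunk$stem$w)))
  for (bl in trunk$blocks) {
    main <- relu(instance_norm(conv2d(y, bl$conv1, stride = bl$stride)))
    main <- instance_norm(conv2d(main, bl$conv2))
    sc <- if (is.null(bl$shortcut)) y else
      instance_norm(conv2d(y, bl$shortcut, stride = bl$stride))
    y <- relu(main + sc)
  }
  y
}

# 3D convolution over the slice (depth) axis: odd-depth kernel, pointwise
# in plane, 'same' zero padding on depth. w3 has dim (kernel_depth, cin, cout).
conv3d_depth <- function(feat, w3, b3) {
  dm <- dim(feat); d <- dm[1]; hw <- dm[2] * dm[3]; cin <- dm[4]
  kd <- dim(w3)[1]; cout <- dim(w3)[3]
  fm <- feat; dim(fm) <- c(d, hw, cin)
  out <- array(0, c(d, hw, cout))
  for (t in seq_len(kd)) {
    s <- t - (kd + 1L) %/% 2L
    dsrc <- intersect(seq_len(d) + s, seq_len(d))
    ddst <- dsrc - s
    sl <- fm[dsrc, , , drop = FALSE]
    dim(sl) <- c(length(dsrc) * hw, cin)
    add <- sl %*% w3[t, , ]
    dim(add) <- c(length(dsrc), hw, cout)
    out[ddst, , ] <- out[ddst, , , drop = FALSE] + add
  }
  out <- sweep(out, 3, b3, "+")
  dim(out) <- c(d, dm[2], dm[3], cout)
  out
}

global_avg_pool <- function(x) {
  dm <- dim(x)
  xm <- x; dim(xm) <- c(prod(dm[1:3]), dm[4])
  colMeans(xm)
}

# Collapsed sufficient statistic of the subtraction branch: because global
# average pooling after the depth-3 convolution is linear in the kernel,
# the branch output equals M %*% W3 + b3 where M holds, per (tap, channel),
# the mean of the depth-shifted trunk feature maps. dim: 3 * n_channels.
trunk_summary <- function(feat) {
  dm <- dim(feat); d <- dm[1]; hw <- dm[2] * dm[3]; cin <- dm[4]
  fm <- feat; dim(fm) <- c(d, hw, cin)
  denom <- d * hw
  M <- matrix(0, 3, cin)
  for (t in 1:3) {
    s <- t - 2L
    dsrc <- intersect(seq_len(d) + s, seq_len(d))
    sl <- fm[dsrc, , , drop = FALSE]
    dim(sl) <- c(length(dsrc) * hw, cin)
    M[t, ] <- colSums(sl) / denom
  }
  as.vector(M)
}

#' Build the subtraction component
#'
#' The shared-weight 2D trunk applied to each of the 7 slices, per-slice
#' feature maps stacked along a new depth axis, one 3D convolution and a
#' 3D global average pool producing exactly 32 features.
#'
#' @param spec a [network_spec()].
#' @param conv3d_kernel_depth depth of the 3D kernel over the slice axis
#'   (default 3).
#' @return object of class `subtraction_net`.
#' @export
build_subtraction_net <- function(spec, conv3d_kernel_depth = 3L) {
  stopifnot(inherits(spec, "network_spec"))
  trunk <- trunk_init(spec)
  cin <- spec$trunk_widths[length(spec$trunk_widths)]
  w3 <- with_seed(derive_seed(spec$seed, "conv3d"), {
    array(stats::rnorm(conv3d_kernel_depth * cin * spec$subtraction_features,
                       0, sqrt(1 / (conv3d_kernel_depth * cin))),
          c(conv3d_kernel_depth, cin, spec$subtraction_features))
  })
  structure(list(spec = spec, trunk = trunk, w3 = w3,
                 b3 = numeric(spec$subtraction_features),
                 kernel_depth = as.integer(conv3d_kernel_depth)),
            class = "subtraction_net")
}

#' Subtraction features for one slice stack
#'
#' Runs the full subtraction component (trunk, 3D convolution, global
#' average pool) and returns the 32-feature vector.
#'
#' @param net a `subtraction_net`.
#' @param stack a `slice_stack` whose slices match the spec input shape.
#' @return numeric vector of length 32.
#' @export
subtraction_features <- function(net, stack) {
  x <- if (inherits(stack, "slice_stack")) stack$slices else stack
  dm <- dim(x)
  if (length(dm) != 3L || dm[3] != net$spec$n_slices ||
      !all(dm[1:2] == net$spec$input_shape)) {
    stop(sprintf("subtraction_features: input must be %d x %d x %d, got %s",
                 net$spec$input_shape[1], net$spec$input_shape[2],
                 net$spec$n_slices, paste(dm, collapse = " x ")), call. = FALSE)
  }
  xs <- aperm(x, c(3, 1, 2)); dim(xs) <- c(dm[3], dm[1], dm[2], 1L)
  feat <- trunk_forward(net$trunk, xs)
  out <- conv3d_depth(feat, net$w3, net$b3)
  global_avg_pool(out)
}

# trunk feature maps for one stack (no resolution of conv3d); internal
trunk_maps <- function(net, stack) {
  x <- if (inherits(stack, "slice_stack")) stack$slices else stack
  dm <- dim(x)
  xs <- aperm(x, c(3, 1, 2)); dim(xs) <- c(dm[3], dm[1], dm[2], 1L)
  trunk_forward(net$trunk, xs)
}
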