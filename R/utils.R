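#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points funnel through
# this so that a single integer seed makes a whole run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream label; keeps every
# derived seed inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Inclusive index extent of TRUE voxels along one array axis; integer(0) when empty.
axis_extent <- function(mask, axis) {
  idx <- which(apply(mask, axis, any))
  if (length(idx) == 0L) return(integer(0))
  range(idx)
}
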