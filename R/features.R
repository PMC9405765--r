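# Separable Gaussian smoothing of a 3D field (sigma in voxels, zero-padded
# borders). Used to soften the binary lesion indicator before isosurface
# extraction: interpolated surface vertices then land close to the true
# tissue interface instead of on the voxel staircase.
smooth_field <- function(field, sigma) {
  if (sigma <= 0) return(field)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  dm <- dim(field)
  shift_add <- function(a, axis) {
    out <- array(0, dim = dm)
    for (t in seq_along(k)) {
      s <- t - r - 1L  # shift
      src <- lapply(dm, seq_len)
      dst <- lapply(dm, seq_len)
      n <- dm[axis]
      if (s > 0) { src[[axis]] <- (1 + s):n; dst[[axis]] <- 1:(n - s) }
      if (s < 0) { src[[axis]] <- 1:(n + s); dst[[axis]] <- (1 - s):n }
      out[dst[[1]], dst[[2]], dst[[3]]] <- out[dst[[1]], dst[[2]], dst[[3]]] +
        k[t] * a[src[[1]], src[[2]], src[[3]]]
    }
    out
  }
  for (axis in 1:3) field <- shift_add(field, axis)
  field
}

# cube corner offsets, corners 1..8 (bit order x, y, z)
.mt_corner <- cbind(x = c(0, 1, 0, 1, 0, 1, 0, 1),
                    y = c(0, 0, 1, 1, 0, 0, 1, 1),
                    z = c(0, 0, 0, 0, 1, 1, 1, 1))
# six-tetrahedra decomposition of the cube around the 1-8 diagonal
.mt_tets <- rbind(c(1, 6, 2, 8), c(1, 2, 4, 8), c(1, 4, 3, 8),
                  c(1, 3, 7, 8), c(1, 7, 5, 8), c(1, 5, 6, 8))

#' Isosurface area of a 3D binary mask
#'
#' Marching tetrahedra over the (optionally Gaussian-smoothed) mask
#' indicator at level 0.5: each boundary cube is split into six tetrahedra,
#' surface vertices are linearly interpolated along sign-changing edges,
#' and triangle areas are accumulated in physical units using the voxel
#' spacing. The field is zero-padded so surfaces close at volume borders.
#'
#' @param mask logical (or 0/1 numeric) 3D array.
#' @param spacing voxel spacing in mm.
#' @param level iso level (default 0.5).
#' @param smooth_sigma Gaussian pre-smoothing SD in voxels (default 1;
#'   0 disables smoothing and measures the staircase surface).
#' @return surface area in mm^2.
#' @export
surface_area <- function(mask, spacing = c(1, 1, 1), level = 0.5, smooth_sigma = 1) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (!any(mask)) return(0)
  dm <- dim(mask)
  f <- array(0, dm + 2L)
  f[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- as.numeric(mask)
  f <- smooth_field(f, smooth_sigma)
  if (max(f) <= level) {
    # object too small to survive smoothing: measure the raw indicator
    f <- array(0, dm + 2L)
    f[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- as.numeric(mask)
  }
  pd <- dim(f)

  # cells whose 8 corners straddle the level
  inside <- f > level
  corner_slice <- function(a, cx, cy, cz) {
    a[(1 + cx):(pd[1] - 1 + cx), (1 + cy):(pd[2] - 1 + cy), (1 + cz):(pd[3] - 1 + cz)]
  }
  acc_any <- array(FALSE, pd - 1L); acc_all <- array(TRUE, pd - 1L)
  for (cc in 1:8) {
    sl <- corner_slice(inside, .mt_corner[cc, 1], .mt_corner[cc, 2], .mt_corner[cc, 3])
    acc_any <- acc_any | sl
    acc_all <- acc_all & sl
  }
  cells <- which(acc_any & !acc_all)
  if (length(cells) == 0L) return(0)
  base <- arrayInd(cells, pd - 1L)

  # corner values and physical positions for the mixed cells
  vals <- matrix(0, length(cells), 8L)
  for (cc in 1:8) {
    lin <- (base[, 1] + .mt_corner[cc, 1]) +
      (base[, 2] + .mt_corner[cc, 2] - 1L) * pd[1] +
      (base[, 3] + .mt_corner[cc, 3] - 1L) * pd[1] * pd[2]
    vals[, cc] <- f[lin]
  }
  pos <- function(cc) {
    cbind((base[, 1] + .mt_corner[cc, 1]) * spacing[1],
          (base[, 2] + .mt_corner[cc, 2]) * spacing[2],
          (base[, 3] + .mt_corner[cc, 3]) * spacing[3])
  }
  interp <- function(fa, fb, pa, pb) pa + ((level - fa) / (fb - fa)) * (pb - pa)
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }

  total <- 0
  for (tt in seq_len(nrow(.mt_tets))) {
    vid <- .mt_tets[tt, ]
    tv <- vals[, vid, drop = FALSE]
    tin <- tv > level
    code <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    for (cd in setdiff(unique(code), c(0L, 15L))) {
      rows <- which(code == cd)
      bits <- as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))
      ins <- which(bits); outs <- which(!bits)
      P <- lapply(1:4, function(j) pos(vid[j])[rows, , drop = FALSE])
      V <- tv[rows, , drop = FALSE]
      if (length(ins) == 1L || length(ins) == 3L) {
        apex <- if (length(ins) == 1L) ins else outs
        rest <- setdiff(1:4, apex)
        e <- lapply(rest, function(j)
          interp(V[, apex], V[, j], P[[apex]], P[[j]]))
        total <- total + sum(tri_area(e[[1]], e[[2]], e[[3]]))
      } else {  # two in, two out: quad split into two triangles
        a <- ins[1]; b <- ins[2]; c <- outs[1]; d <- outs[2]
        pac <- interp(V[, a], V[, c], P[[a]], P[[c]])
        pad_ <- interp(V[, a], V[, d], P[[a]], P[[d]])
        pbc <- interp(V[, b], V[, c], P[[b]], P[[c]])
        pbd <- interp(V[, b], V[, d], P[[b]], P[[d]])
        total <- total + sum(tri_area(pac, pad_, pbd)) + sum(tri_area(pac, pbd, pbc))
      }
    }
  }
  total
}

#' Volumetric lesion features
#'
#' The five named lesion descriptors, in physical units, computed from the
#' largest lesion region: tumor volume (mm^3, voxel count times voxel
#' volume), surface area (mm^2, isosurface of the binary mask), number of
#' separate regions, intensity ratio (mean lesion intensity over mean
#' non-lesion breast intensity on the water-suppression Dixon contrast),
#' and spread (mm, the sum over x, y, z of the maximum lesion extent,
#' counted as inclusive index range + 1 times spacing).
#'
#' @param largest logical mask of the largest lesion region.
#' @param n_regions total number of separate lesion regions.
#' @param intensity_volume the Dixon volume used for the intensity ratio
#'   (water-suppression contrast, i.e. the fat-visible volume, by default).
#' @param breast_mask tumor-side breast mask (must contain the lesion).
#' @param spacing voxel spacing in mm.
#' @param smooth_sigma passed to [surface_area()].
#' @return object of class `volumetric_features`: a named list with
#'   `tumor_volume`, `surface_area`, `n_regions`, `intensity_ratio`,
#'   `spread`, and `lesion_missing` (TRUE when the mask is empty; all
#'   geometric entries are then zero and the ratio NA).
#' @export
compute_features <- function(largest, n_regions, intensity_volume, breast_mask,
                             spacing, smooth_sigma = 1) {
  stopifnot(identical(dim(largest), dim(breast_mask)),
            identical(dim(largest), dim(intensity_volume)),
            all(spacing > 0))
  if (any(largest & !breast_mask)) {
    stop("lesion mask must lie inside the breast mask", call. = FALSE)
  }
  if (!any(largest)) {
    out <- list(tumor_volume = 0, surface_area = 0, n_regions = as.integer(n_regions),
                intensity_ratio = NA_real_, spread = 0, lesion_missing = TRUE)
    return(structure(out, class = "volumetric_features"))
  }
  voxvol <- prod(spacing)
  vol <- sum(largest) * voxvol
  sa <- surface_area(largest, spacing, smooth_sigma = smooth_sigma)
  other <- breast_mask & !largest
  ratio <- if (!any(other)) NA_real_ else
    mean(intensity_volume[largest]) / mean(intensity_volume[other])
  spread <- 0
  for (axis in 1:3) {
    ext <- axis_extent(largest, axis)
    spread <- spread + (diff(ext) + 1) * spacing[axis]
  }
  structure(list(tumor_volume = vol, surface_area = sa,
                 n_regions = as.integer(n_regions),
                 intensity_ratio = ratio, spread = spread,
                 lesion_missing = FALSE),
            class = "volumetric_features")
}

#' Full lesion feature extraction from a segmented study
#'
#' Runs [count_regions()] on the lesion mask and [compute_features()] on
#' the largest region.
#'
#' @param masks a `mask_set`.
#' @param study the `mri_study` the masks came from.
#' @param intensity_volume `"fat"` (water-suppression contrast, default) or
#'   `"water"`.
#' @param smooth_sigma passed to [surface_area()].
#' @return a `volumetric_features` object.
#' @export
extract_volumetric_features <- function(masks, study,
                                        intensity_volume = c("fat", "water"),
                                        smooth_sigma = 1) {
  intensity_volume <- match.arg(intensity_volume)
  cr <- count_regions(masks$lesion)
  compute_features(cr$largest, cr$n_regions,
                   study$volumes[[intensity_volume]], masks$tumor_side,
                   study$spacing, smooth_sigma = smooth_sigma)
}

#' Assemble the Dixon-ADC input vector
#'
#' Fixed ordering: the five volumetric features, the lesion-missing flag,
#' then the configured clinical metadata fields. Missing entries (NA) are
#' left in place here; imputation by training-fold means happens at model
#' training time (see [impute_by_train_means()]).
#'
#' @param features a `volumetric_features` object.
#' @param clinical_row one-row data.frame (or list) of clinical metadata.
#' @param metadata_fields which clinical fields to append.
#' @return named numeric vector of constant length across a cohort.
#' @export
assemble_dixon_vector <- function(features, clinical_row,
                                  metadata_fields = c("age", "bmi",
                                                      "tumor_size_mm", "tumor_grade")) {
  stopifnot(inherits(features, "volumetric_features"))
  missing_fields <- setdiff(metadata_fields, names(clinical_row))
  if (length(missing_fields)) {
    stop("unknown clinical metadata field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  meta <- vapply(metadata_fields, function(f) as.numeric(clinical_row[[f]]), numeric(1))
  c(tumor_volume = features$tumor_volume,
    surface_area = features$surface_area,
    n_regions = as.numeric(features$n_regions),
    intensity_ratio = features$intensity_ratio,
    spread = features$spread,
    lesion_missing = as.numeric(features$lesion_missing),
    meta)
}

#' Impute missing entries of a feature matrix with training-row means
#'
#' Column means are computed on the training rows only and substituted for
#' NA entries everywhere; a column with no observed training value errors.
#'
#' @param x numeric matrix.
#' @param train_rows logical or integer index of training rows.
#' @return list with `x` (imputed matrix) and `means` (training means used).
#' @export
impute_by_train_means <- function(x, train_rows) {
  mu <- colMeans(x[train_rows, , drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(mu))) {
    stop("column(s) entirely missing in training rows: ",
         paste(colnames(x)[!is.finite(mu)], collapse = ", "), call. = FALSE)
  }
  for (j in seq_len(ncol(x))) x[which(is.na(x[, j])), j] <- mu[[j]]
  list(x = x, means = mu)
}
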