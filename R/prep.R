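#' Extract the significant slice and its six neighbours
#'
#' Returns the seven axial slices at indices s-3 ... s+3 of the annotated
#' subtraction volume, in acquisition order with the significant slice in
#' the center. Indices falling outside the volume are clamped by
#' edge-replication (the terminal slice is repeated), preserving the
#' seven-slice contract; when that happens the result is flagged.
#'
#' @param study an `mri_study` whose annotations name the selected
#'   subtraction volume and significant slice.
#' @return list with `slices` (x-by-y-by-7 array), `indices` (source slice
#'   indices after clamping) and `clamped` (logical).
#' @export
extract_slices <- function(study) {
  stopifnot(inherits(study, "mri_study"))
  ann <- study$annotations
  vol <- study$volumes$subtraction[[ann$selected_subtraction]]
  nz <- dim(vol)[3]
  s <- ann$significant_slice
  stopifnot(s >= 1L, s <= nz)
  idx <- s + (-3:3)
  clamped <- any(idx < 1L | idx > nz)
  idx <- pmin(pmax(idx, 1L), nz)
  list(slices = vol[, , idx, drop = FALSE], indices = idx, clamped = clamped)
}

#' Slice undersampling for overlapping acquisitions
#'
#' When the slice thickness exceeds the slice spacing, adjacent slices
#' overlap; every k-th slice with `k = ceiling(thickness / spacing)` is
#' retained. Without overlap all slices are kept.
#'
#' @param n_slices number of slices in the volume.
#' @param slice_spacing center-to-center slice distance (mm).
#' @param slice_thickness acquired slice thickness (mm).
#' @return integer vector of retained slice indices.
#' @export
undersample_overlap <- function(n_slices, slice_spacing, slice_thickness) {
  stopifnot(slice_spacing > 0, slice_thickness > 0, n_slices >= 1)
  k <- if (slice_thickness > slice_spacing)
    as.integer(ceiling(slice_thickness / slice_spacing)) else 1L
  seq.int(1L, n_slices, by = k)
}

#' Standardize raw subtraction slices into the CNN input stack
#'
#' The standardization chain of the subtraction branch: (1) vertical crop
#' at the mid-sagittal column, keeping only the tumor-side half; (2) for
#' right-sided tumors, horizontal flip so the breast faces the canonical
#' (left-side) direction in every output; (3) removal of non-breast margin
#' rows/columns whose maximum intensity across the stack falls below
#' `threshold_frac` of the stack maximum (trimmed from the edges only);
#' (4) bilinear resize to `out_shape`; (5) min-max normalization of the
#' whole stack to [0, 1].
#'
#' Standardization is defined on raw bilateral slices; applying it to an
#' already-standardized `slice_stack` is the identity.
#'
#' @param raw x-by-y-by-7 array of raw slices (or the list returned by
#'   [extract_slices()]), both breasts in frame.
#' @param tumor_side "left" or "right".
#' @param out_shape output image size (default the production 512 x 256;
#'   reduced desk-scale profiles keep the 2:1 aspect).
#' @param threshold_frac breast-presence threshold as a fraction of the
#'   stack maximum.
#' @param source_indices optional source slice indices for provenance.
#' @return object of class `slice_stack`: `slices` (out_shape x 7 array in
#'   [0,1]), `source_indices`, `tumor_side`, `flipped`, `crop_box`.
#' @export
standardize_slices <- function(raw, tumor_side, out_shape = c(512L, 256L),
                               threshold_frac = 0.05, source_indices = NULL) {
  if (inherits(raw, "slice_stack")) return(raw)
  if (is.list(raw) && !is.null(raw$slices)) {
    if (is.null(source_indices)) source_indices <- raw$indices
    raw <- raw$slices
  }
  stopifnot(length(dim(raw)) == 3L, dim(raw)[3] == 7L,
            tumor_side %in% c("left", "right"))
  nx <- dim(raw)[1]
  half <- side_half(nx, tumor_side)
  x <- raw[half, , , drop = FALSE]
  flipped <- tumor_side == "right"
  if (flipped) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]

  # margin trim: drop contiguous low-intensity rows/cols at the edges
  mx <- max(x)
  thr <- threshold_frac * mx
  row_keep <- apply(x, 1, max) >= thr
  col_keep <- apply(x, 2, max) >= thr
  if (!any(row_keep) || !any(col_keep) || mx <= 0) {
    stop("standardize_slices: degenerate input, no breast signal above threshold",
         call. = FALSE)
  }
  rr <- range(which(row_keep)); cc <- range(which(col_keep))
  x <- x[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]

  out <- array(0, dim = c(out_shape, 7L))
  for (s in 1:7) {
    out[, , s] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(x[, , s]), w = out_shape[1], h = out_shape[2]))
  }
  rng <- range(out)
  if (rng[2] - rng[1] <= 0) {
    stop("standardize_slices: degenerate input, constant intensity", call. = FALSE)
  }
  out <- (out - rng[1]) / (rng[2] - rng[1])
  structure(list(slices = out,
                 source_indices = source_indices,
                 tumor_side = tumor_side, flipped = flipped,
                 crop_box = list(rows = rr, cols = cc, half = range(half))),
            class = "slice_stack")
}

#' Prepare the CNN slice stack for one study
#'
#' [extract_slices()] followed by [standardize_slices()].
#' @param study an `mri_study`.
#' @param out_shape passed to [standardize_slices()].
#' @return a `slice_stack`.
#' @export
prepare_slice_stack <- function(study, out_shape = c(512L, 256L)) {
  ex <- extract_slices(study)
  standardize_slices(ex$slices, study$annotations$tumor_side,
                     out_shape = out_shape, source_indices = ex$indices)
}
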