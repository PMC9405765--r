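#' Specify an mpMRI phantom
#'
#' A phantom is a voxel grid holding two ellipsoidal breasts (a fat/gland
#' tissue mixture) and zero or more ellipsoidal lesions, rendered into the
#' four volume types of a multiparametric breast MRI study: DCE subtraction,
#' ADC, Dixon water-only and Dixon fat-only. Tissue classes are given
#' per-volume-type intensity means far enough apart (at least
#' `3 * noise_sd`) that clustering can recover them by construction; lesions
#' are bright on subtraction, water-only and ADC, matching the selection
#' rule the segmentation stage relies on.
#'
#' @param shape integer grid size (3 axes: x = left-right, y =
#'   anterior-posterior, z = slice axis).
#' @param spacing voxel spacing in mm (3 axes, all positive).
#' @param breasts list with elements `left` and `right`, each a list with
#'   `center` (mm) and `semiaxes` (mm).
#' @param fat_fraction fraction of breast-tissue voxels drawn as fat (0-1).
#' @param lesions list of lesions, each a list with `center` (mm),
#'   `semiaxes` (mm) and `side` ("left" or "right"). May be empty.
#' @param intensity_means numeric matrix (tissue x volume type) of class
#'   mean intensities, rows `background, fat, gland, lesion`, columns
#'   `subtraction, adc, water, fat`.
#' @param noise_sd per-volume-type additive Gaussian noise SD, recycled to
#'   length 4.
#' @param seed integer random seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 32L, 20L),
                         spacing = c(3, 3, 3),
                         breasts = NULL,
                         fat_fraction = 0.55,
                         lesions = NULL,
                         intensity_means = default_intensity_means(),
                         noise_sd = 5,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive on all axes", call. = FALSE)
  }
  fov <- shape * spacing
  if (is.null(breasts)) {
    semi <- pmin(c(0.21, 0.40, 0.44) * fov, c(45, 42, 30))
    breasts <- list(
      left  = list(center = c(0.25 * fov[1], 0.47 * fov[2], 0.5 * fov[3]), semiaxes = semi),
      right = list(center = c(0.75 * fov[1], 0.47 * fov[2], 0.5 * fov[3]), semiaxes = semi)
    )
  }
  if (is.null(lesions)) {
    lesions <- list(list(center = breasts$left$center + c(5, 3, 0),
                         semiaxes = c(15, 12, 12), side = "left"))
  }
  stopifnot(is.list(lesions))
  noise_sd <- rep_len(noise_sd, 4L)
  names(noise_sd) <- colnames(intensity_means)
  for (les in lesions) {
    stopifnot(les$side %in% c("left", "right"))
    br <- breasts[[les$side]]
    # conservative containment test: offset plus lesion semiaxis must fit
    # inside the breast ellipsoid on every axis jointly
    q <- sum(((abs(les$center - br$center) + les$semiaxes) / br$semiaxes)^2)
    if (q > 1) {
      stop("lesion does not fit inside its breast ellipsoid", call. = FALSE)
    }
  }
  # separability invariant: class means per volume type >= 3 noise SD apart
  for (v in colnames(intensity_means)) {
    d <- abs(outer(intensity_means[, v], intensity_means[, v], "-"))
    if (min(d[upper.tri(d)]) < 3 * noise_sd[[v]]) {
      stop(sprintf("intensity means on volume '%s' are closer than 3 noise SD", v),
           call. = FALSE)
    }
  }
  structure(list(shape = shape, spacing = as.numeric(spacing), breasts = breasts,
                 fat_fraction = fat_fraction, lesions = lesions,
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default tissue intensity means for phantom rendering
#'
#' Rows are tissue classes, columns volume types; arbitrary units. Lesions
#' are the brightest class on subtraction, ADC and water-only volumes, and
#' fat tissue dominates the fat-only Dixon volume.
#' @return numeric matrix 4 x 4.
#' @export
default_intensity_means <- function() {
  m <- rbind(background = c(10, 10, 10, 10),
             fat        = c(30, 40, 30, 200),
             gland      = c(50, 80, 150, 30),
             lesion     = c(250, 200, 220, 45))
  colnames(m) <- c("subtraction", "adc", "water", "fat")
  m
}

# Ellipsoid indicator over voxel centers. Coordinates of voxel i along an
# axis are (i - 0.5) * spacing.
ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  cx <- (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(shape[3]) - 0.5) * spacing[3]
  qx <- ((cx - center[1]) / semiaxes[1])^2
  qy <- ((cy - center[2]) / semiaxes[2])^2
  qz <- ((cz - center[3]) / semiaxes[3])^2
  array(outer(outer(qx, qy, "+"), qz, "+") <= 1, dim = shape)
}

#' Generate a phantom mpMRI study with ground truth
#'
#' Renders the phantom described by a [phantom_spec()] into an `mri_study`
#' (four co-registered volume types plus annotations) and a `phantom_truth`
#' (ground-truth masks and analytic lesion geometry). Deterministic given
#' the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier stored in the study annotations.
#' @return list with elements `study` (class `mri_study`) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_phantom <- function(spec, patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; spacing <- spec$spacing
  tissue <- array("background", dim = shape)
  side_mask <- list()
  for (s in c("left", "right")) {
    br <- spec$breasts[[s]]
    side_mask[[s]] <- ellipsoid_mask(shape, spacing, br$center, br$semiaxes)
  }
  breast <- side_mask$left | side_mask$right
  lesion <- array(FALSE, dim = shape)
  for (les in spec$lesions) {
    lesion <- lesion | ellipsoid_mask(shape, spacing, les$center, les$semiaxes)
  }
  lesion <- lesion & breast

  volumes <- with_seed(spec$seed, {
    tissue[breast] <- ifelse(stats::runif(sum(breast)) < spec$fat_fraction,
                             "fat", "gland")
    tissue[lesion] <- "lesion"
    vols <- list()
    for (v in colnames(spec$intensity_means)) {
      base <- spec$intensity_means[tissue, v]
      vols[[v]] <- array(base + stats::rnorm(length(tissue), 0, spec$noise_sd[[v]]),
                         dim = shape)
    }
    vols
  })

  if (length(spec$lesions) > 0L) {
    vox_per_slice <- apply(lesion, 3, sum)
    significant <- which.max(vox_per_slice)
    tumor_side <- spec$lesions[[1L]]$side
    lo <- sapply(1:3, function(a) min(vapply(spec$lesions, function(l) l$center[a] - l$semiaxes[a], 0)))
    hi <- sapply(1:3, function(a) max(vapply(spec$lesions, function(l) l$center[a] + l$semiaxes[a], 0)))
    bbox <- hi - lo
    analytic <- sum(vapply(spec$lesions, function(l) 4 / 3 * pi * prod(l$semiaxes), 0))
  } else {
    significant <- as.integer(ceiling(shape[3] / 2))
    tumor_side <- "left"
    bbox <- c(0, 0, 0)
    analytic <- 0
  }

  study <- structure(list(
    patient_id = patient_id,
    volumes = list(subtraction = list(volumes$subtraction),
                   adc = volumes$adc, water = volumes$water, fat = volumes$fat),
    spacing = spacing,
    annotations = list(tumor_side = tumor_side,
                       selected_subtraction = 1L,
                       significant_slice = as.integer(significant),
                       slice_spacing = spacing[3],
                       slice_thickness = spacing[3])
  ), class = "mri_study")

  truth <- structure(list(
    lesion_mask = lesion,
    breast_mask_left = side_mask$left,
    breast_mask_right = side_mask$right,
    tissue = tissue,
    analytic_volume = analytic,
    bbox_extent = bbox,
    lesion_count = length(spec$lesions)
  ), class = "phantom_truth")

  list(study = study, truth = truth)
}

#' @export
print.mri_study <- function(x, ...) {
  cat("mri_study", x$patient_id, "-", paste(dim(x$volumes$water), collapse = "x"),
      "voxels, spacing", paste(signif(x$spacing, 3), collapse = "x"), "mm,",
      "tumor side:", x$annotations$tumor_side, "\n")
  invisible(x)
}
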