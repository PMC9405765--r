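#' Write an mpMRI study to NIfTI files with a JSON manifest
#'
#' One NIfTI-1 file per volume type (spacing recorded in the header), truth
#' masks as 0/1 NIfTI volumes when supplied, and a JSON manifest linking the
#' patient ID to volume files and annotations.
#'
#' @param study an `mri_study`.
#' @param dir output directory (created if needed).
#' @param truth optional `phantom_truth`; its masks are written alongside.
#' @return invisibly, the manifest path.
#' @export
write_mri_study <- function(study, dir, truth = NULL) {
  stopifnot(inherits(study, "mri_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- study$patient_id
  files <- list()
  put <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- study$spacing
    path <- file.path(dir, sprintf("%s_%s.nii.gz", pid, name))
    RNifti::writeNifti(img, path)
    basename(path)
  }
  for (i in seq_along(study$volumes$subtraction)) {
    files[[sprintf("subtraction_%d", i)]] <- put(study$volumes$subtraction[[i]],
                                                 sprintf("subtraction_%d", i))
  }
  for (v in c("adc", "water", "fat")) files[[v]] <- put(study$volumes[[v]], v)
  if (!is.null(truth)) {
    files$lesion_mask <- put(truth$lesion_mask, "lesion_mask")
    files$breast_mask_left <- put(truth$breast_mask_left, "breast_mask_left")
    files$breast_mask_right <- put(truth$breast_mask_right, "breast_mask_right")
  }
  manifest <- list(patient_id = pid, spacing = study$spacing,
                   n_subtraction = length(study$volumes$subtraction),
                   files = files, annotations = study$annotations)
  mpath <- file.path(dir, sprintf("%s_manifest.json", pid))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read an mpMRI study back from a manifest
#'
#' @param manifest_path path to a manifest written by [write_mri_study()].
#' @return an `mri_study` (truth masks, if present, attached as attribute
#'   `truth_masks`).
#' @export
read_mri_study <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  get <- function(name) {
    arr <- RNifti::readNifti(file.path(dir, m$files[[name]]))
    array(as.numeric(arr), dim = dim(arr))
  }
  subs <- lapply(seq_len(m$n_subtraction), function(i) get(sprintf("subtraction_%d", i)))
  ann <- m$annotations
  ann$selected_subtraction <- as.integer(ann$selected_subtraction)
  ann$significant_slice <- as.integer(ann$significant_slice)
  study <- structure(list(
    patient_id = m$patient_id,
    volumes = list(subtraction = subs, adc = get("adc"),
                   water = get("water"), fat = get("fat")),
    spacing = as.numeric(m$spacing),
    annotations = ann
  ), class = "mri_study")
  if (!is.null(m$files$lesion_mask)) {
    attr(study, "truth_masks") <- list(
      lesion_mask = get("lesion_mask") > 0.5,
      breast_mask_left = get("breast_mask_left") > 0.5,
      breast_mask_right = get("breast_mask_right") > 0.5)
  }
  study
}

#' Write segmentation masks and report for one study
#'
#' The three masks as 0/1 NIfTI volumes plus the per-study segmentation
#' report (cluster centers, overlap fractions, warnings) as JSON.
#'
#' @param seg result of [segment_study()].
#' @param study the segmented `mri_study` (provides ID and spacing).
#' @param dir output directory.
#' @return invisibly, the report path.
#' @export
write_segmentation <- function(seg, study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- study$patient_id
  for (m in c("bilateral", "tumor_side", "lesion")) {
    img <- RNifti::asNifti(seg$masks[[m]] * 1)
    RNifti::pixdim(img) <- study$spacing
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_mask_%s.nii.gz", pid, m)))
  }
  rpath <- file.path(dir, sprintf("%s_segmentation.json", pid))
  jsonlite::write_json(list(patient_id = pid, report = seg$report),
                       rpath, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rpath)
}

#' Write a cohort table to CSV
#'
#' Plain-text companion to the NIfTI manifests; the header is the column
#' set documented in [generate_cohort()].
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
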