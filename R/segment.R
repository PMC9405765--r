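#' Assemble and validate the three segmentation masks
#'
#' Enforces the nesting invariant lesion ⊆ tumor-side breast ⊆ bilateral
#' breast (the lesion mask is intersected with the tumor-side mask, the
#' tumor-side mask with the bilateral mask) and checks that all masks share
#' one grid.
#'
#' @param bilateral,tumor_side,lesion logical 3D arrays on one grid.
#' @return object of class `mask_set`.
#' @export
mask_set <- function(bilateral, tumor_side, lesion) {
  stopifnot(identical(dim(bilateral), dim(tumor_side)),
            identical(dim(bilateral), dim(lesion)))
  tumor_side <- tumor_side & bilateral
  lesion <- lesion & tumor_side
  structure(list(bilateral = bilateral, tumor_side = tumor_side, lesion = lesion),
            class = "mask_set")
}

# Half-grid index range of one breast side along the left-right (first) axis.
# Convention: "left" is the lower-index half (phantoms place the left breast
# at low x).
side_half <- function(nx, side) {
  mid <- nx %/% 2
  if (side == "left") seq_len(mid) else (mid + 1L):nx
}

#' Phase-1 segmentation: breast tissue from Dixon water/fat volumes
#'
#' Clusters every voxel's 2-channel feature (water-only, fat-only intensity)
#' with fuzzy c-means. The cluster whose center has the lowest total
#' intensity is taken as image background; every cluster whose total
#' intensity exceeds that background by `contrast_factor` is labelled breast
#' tissue (fat-dominant and water-dominant parenchyma both count). The
#' tumor-side mask is the bilateral mask restricted to the annotated side's
#' half-grid.
#'
#' @param water,fat co-registered 3D volumes on one grid.
#' @param tumor_side "left" or "right".
#' @param k number of clusters for phase 1 (default 3: background /
#'   fat-dominant / water-dominant).
#' @param m,tol,max_iter,seed fuzzy c-means controls, see [fcm()].
#' @param contrast_factor a cluster counts as tissue when its total center
#'   intensity exceeds `contrast_factor` times the background cluster's; on
#'   an all-background volume no cluster passes and empty masks are
#'   returned with a warning.
#' @return list with `bilateral`, `tumor_side` (logical masks), `fcm`
#'   (phase-1 [fcm()] result) and `report` (cluster centers and labels).
#' @export
segment_breast <- function(water, fat, tumor_side = "left", k = 3L, m = 2,
                           tol = 1e-4, max_iter = 300L, seed = 1L,
                           contrast_factor = 1.5) {
  stopifnot(identical(dim(water), dim(fat)), tumor_side %in% c("left", "right"))
  feats <- cbind(water = as.vector(water), fat = as.vector(fat))
  res <- fcm(feats, k = k, m = m, tol = tol, max_iter = max_iter, seed = seed)
  totals <- rowSums(res$centers)
  bg <- which.min(totals)
  tissue_clusters <- which(totals > contrast_factor * totals[bg])
  if (length(tissue_clusters) == 0L) {
    warning("segment_breast: no cluster exceeds the background intensity; ",
            "returning empty masks")
    bilateral <- array(FALSE, dim = dim(water))
  } else {
    bilateral <- array(res$hard %in% tissue_clusters, dim = dim(water))
  }
  ts <- array(FALSE, dim = dim(water))
  half <- side_half(dim(water)[1], tumor_side)
  ts[half, , ] <- bilateral[half, , ]
  list(bilateral = bilateral, tumor_side = ts, fcm = res,
       report = list(centers = res$centers, background_cluster = bg,
                     tissue_clusters = tissue_clusters))
}

#' Phase-2 segmentation: lesion voxels inside the tumor-side breast
#'
#' Voxels inside the tumor-side breast mask are clustered again with fuzzy
#' c-means on (water-only, ADC) intensities — water-only alone when no ADC
#' volume is available. The "high-intensity area" is the set of in-mask
#' voxels above the `percentile` quantile on ADC *and* on water-only
#' (intersection); the cluster(s) maximizing their Dice overlap with that
#' area become the lesion mask, provided the best overlap reaches
#' `min_overlap` — otherwise an empty mask is returned with a warning (the
#' no-lesion path). Dice (rather than the fraction of cluster voxels that
#' are high-intensity) keeps the rule symmetric: it neither rejects
#' lesions larger than the top-percentile area nor latches onto the noise
#' tail of normal parenchyma. Phase-2 clustering is multi-start (center
#' initializations across the full intensity range and at an
#' upper-quantile spread); the restart with the lowest final objective is
#' kept, which prevents the local minimum that merges a large lesion with
#' parenchyma.
#'
#' @param water 3D water-only volume.
#' @param adc 3D ADC volume or NULL when unavailable.
#' @param breast list with at least `tumor_side` (from [segment_breast()]),
#'   or a `mask_set`.
#' @param k,m,tol,max_iter,seed fuzzy c-means controls.
#' @param percentile quantile defining "high intensity" (default 0.95, i.e.
#'   the top 5% of in-mask intensities).
#' @param min_overlap smallest Dice overlap that still counts as a lesion
#'   cluster.
#' @return list with `lesion` (logical mask), `fcm`, and `report`
#'   (Dice overlap per cluster, selected clusters, warnings).
#' @export
segment_lesion <- function(water, adc = NULL, breast, k = 3L, m = 2,
                           tol = 1e-4, max_iter = 300L, seed = 1L,
                           percentile = 0.95, min_overlap = 0.15) {
  ts_mask <- if (inherits(breast, "mask_set")) breast$tumor_side else breast$tumor_side
  stopifnot(identical(dim(water), dim(ts_mask)))
  if (!any(ts_mask)) stop("segment_lesion: tumor-side breast mask is empty", call. = FALSE)
  idx <- which(ts_mask)
  w <- water[idx]
  feats <- if (is.null(adc)) cbind(water = w) else cbind(water = w, adc = adc[idx])
  inits <- list(seq(0, 1, length.out = k),
                c(rep(0.02, max(0, k - 2L)), 0.7, 1)[seq_len(k)])
  runs <- lapply(inits, function(pr)
    fcm(feats, k = k, m = m, tol = tol, max_iter = max_iter, seed = seed,
        init_probs = sort(pr)))
  res <- runs[[which.min(vapply(runs, function(r) r$objective[length(r$objective)],
                                numeric(1)))]]

  high <- w >= stats::quantile(w, percentile, names = FALSE)
  if (!is.null(adc)) {
    a <- adc[idx]
    high <- high & (a >= stats::quantile(a, percentile, names = FALSE))
  }
  overlap <- vapply(seq_len(k), function(j) {
    in_cl <- res$hard == j
    if (!any(in_cl) || !any(high)) return(0)
    2 * sum(in_cl & high) / (sum(in_cl) + sum(high))
  }, numeric(1))
  best <- max(overlap)
  lesion <- array(FALSE, dim = dim(water))
  if (!any(high) || best < min_overlap) {
    warning("segment_lesion: no cluster overlaps the high-intensity area; ",
            "returning an empty lesion mask")
    selected <- integer(0)
  } else {
    selected <- which(overlap >= best - 1e-12)
    lesion[idx[res$hard %in% selected]] <- TRUE
  }
  list(lesion = lesion, fcm = res,
       report = list(overlap_fraction = overlap, selected_clusters = selected,
                     high_intensity_voxels = sum(high),
                     adc_used = !is.null(adc)))
}

#' Run both segmentation phases on an mpMRI study
#'
#' Convenience wrapper producing the full [mask_set()] plus a JSON-ready
#' segmentation report.
#'
#' @param study an `mri_study`.
#' @param use_adc include the ADC volume in the lesion phase (default TRUE).
#' @param ... passed to [segment_breast()] and [segment_lesion()].
#' @param seed seed forwarded to both phases.
#' @return list with `masks` (a `mask_set`) and `report`.
#' @export
segment_study <- function(study, use_adc = TRUE, seed = 1L, ...) {
  stopifnot(inherits(study, "mri_study"))
  br <- segment_breast(study$volumes$water, study$volumes$fat,
                       tumor_side = study$annotations$tumor_side, seed = seed, ...)
  les <- segment_lesion(study$volumes$water,
                        adc = if (use_adc) study$volumes$adc else NULL,
                        breast = br, seed = seed, ...)
  masks <- mask_set(br$bilateral, br$tumor_side, les$lesion)
  list(masks = masks,
       report = list(phase1 = br$report, phase2 = les$report))
}
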