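#' Segmentation parameters
#'
#' The HU window (-950, -450) delimits functionally normal aerated lung:
#' below it lies pure air (pneumothorax, airway), above it ground-glass and
#' consolidated contusion. The pneumothorax detector relies on a 3D mean
#' filter: homogeneous pleural air stays at air attenuation after
#' smoothing, whereas aerated alveoli (an air/tissue mix with local
#' heterogeneity around -750 HU) are pulled above the air threshold.
#'
#' @param normal_hu_window `(low, high)` HU bounds of normal lung,
#'   inclusive at both ends; default `c(-950, -450)`.
#' @param air_hu_max HU at or below which a (filtered) voxel counts as pure
#'   air; default -950.
#' @param smoothing_kernel odd edge length (voxels) of the cubic mean
#'   filter; default 5. Values below 3 disable the alveolar suppression the
#'   detector depends on and are only useful to demonstrate that failure.
#' @param min_component_ml connected components smaller than this are
#'   discarded; default 1 mL.
#' @param closing_radius_mm morphological closing radius for the total-lung
#'   surrogate; default 5 mm.
#' @param total_lung_hu_max upper HU bound for lung-candidate voxels in the
#'   total-lung surrogate; default -250.
#' @return A `seg_params` list.
#' @export
seg_params <- function(normal_hu_window = c(-950, -450),
                       air_hu_max = -950,
                       smoothing_kernel = 5L,
                       min_component_ml = 1.0,
                       closing_radius_mm = 5,
                       total_lung_hu_max = -250) {
  if (length(normal_hu_window) != 2L || normal_hu_window[1] >= normal_hu_window[2])
    cv_stop("cv_config_error", "normal_hu_window must satisfy low < high")
  smoothing_kernel <- as.integer(smoothing_kernel)
  if (smoothing_kernel < 1L || smoothing_kernel %% 2L == 0L)
    cv_stop("cv_config_error", "smoothing_kernel must be a positive odd integer")
  if (smoothing_kernel < 3L)
    warning("smoothing_kernel < 3 disables alveolar suppression; pneumothorax detection will false-positive on aerated lung")
  if (min_component_ml < 0 || closing_radius_mm <= 0)
    cv_stop("cv_config_error", "component volume and closing radius must be positive")
  structure(list(
    normal_hu_window = as.numeric(normal_hu_window),
    air_hu_max = as.numeric(air_hu_max),
    smoothing_kernel = smoothing_kernel,
    min_component_ml = as.numeric(min_component_ml),
    closing_radius_mm = as.numeric(closing_radius_mm),
    total_lung_hu_max = as.numeric(total_lung_hu_max)
  ), class = "seg_params")
}

# Labels of components touching given border faces of the grid.
border_labels <- function(lab, faces) {
  d <- dim(lab)
  out <- integer(0)
  if ("y" %in% faces) out <- c(out, lab[, 1, ], lab[, d[2], ])
  if ("x" %in% faces) out <- c(out, lab[, , 1], lab[, , d[3]])
  if ("z" %in% faces) out <- c(out, lab[1, , ], lab[d[1], , ])
  unique(out[out > 0])
}

#' Rule-based total-lung surrogate segmentation
#'
#' Stands in for learned or hand-labelled whole-lung masks: voxels at or
#' below `total_lung_hu_max` inside the body envelope are lung candidates;
#' exterior air is removed as the components connected to the lateral
#' (x/y) volume borders; the lungs are the components at least 20% the
#' size of the largest (so fused lungs or two separate ones both work,
#' while the trachea and small air pockets drop out); morphological
#' closing and 3D hole filling then pull ground-glass and consolidated
#' contusion interior to the lung back into the mask.
#'
#' @param ct a [ct_volume()].
#' @param params a [seg_params()].
#' @return total-lung [mask_volume()].
#' @export
segment_total_lung <- function(ct, params = seg_params()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(params, "seg_params"))
  hu <- ct$voxels
  cand <- hu <= params$total_lung_hu_max
  vox_ml <- voxel_volume_ml(ct)
  if (any(cand)) {
    lab <- label_components(cand, 6L)
    drop <- border_labels(lab, c("x", "y"))
    cand <- cand & !array(lab %in% drop, dim = dim(lab))
  }
  if (any(cand)) {
    lab <- label_components(cand, 6L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= 0.2 * max(sizes))
    keep <- keep[order(-sizes[keep], keep)]        # size, then label order
    cand <- array(lab %in% keep, dim = dim(lab))
  }
  if (sum(cand) * vox_ml < 100)
    cv_stop("cv_segmentation_error",
            "no lung-sized air component found (%.1f mL below the 100 mL floor)",
            sum(cand) * vox_ml)
  closed <- binary_close(cand, params$closing_radius_mm, ct$spacing)
  filled <- fill_holes(closed)
  mask_volume(filled, ct$spacing)
}

#' Normal-lung segmentation by HU window
#'
#' Voxels within the total-lung mask whose HU lies in the normal window
#' (inclusive at both bounds), minus connected components smaller than
#' `min_component_ml`.
#'
#' @param ct a [ct_volume()].
#' @param total total-lung [mask_volume()] (surrogate or external).
#' @param params a [seg_params()].
#' @return normal-lung [mask_volume()].
#' @export
segment_normal_lung <- function(ct, total, params = seg_params()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(total, "mask_volume"))
  check_same_grid(total, ct, "total-lung mask")
  w <- params$normal_hu_window
  m <- total$voxels & ct$voxels >= w[1] & ct$voxels <= w[2]
  m <- drop_small_components(m, params$min_component_ml, ct$spacing)
  mask_volume(m, ct$spacing)
}

#' Pneumothorax detection by 3D smoothing filter
#'
#' A cubic mean filter of edge `smoothing_kernel` is applied to the HU
#' volume. Homogeneous pure-air pockets survive the smoothing at or below
#' `air_hu_max`; aerated alveoli are pulled above it. Raw-air connected
#' components that contain at least one such smoothed core are retained at
#' their full raw-air extent (the filter detects, the unsmoothed air mask
#' delineates, so the measured volume is not eroded by the kernel
#' half-width). Components connected to the superior or inferior volume
#' faces (trachea / exterior air) are excluded, the result is clipped to
#' the total-lung mask, and components below `min_component_ml` dropped.
#'
#' @param ct a [ct_volume()].
#' @param total total-lung [mask_volume()].
#' @param params a [seg_params()].
#' @return pneumothorax [mask_volume()].
#' @export
detect_pneumothorax <- function(ct, total, params = seg_params()) {
  stopifnot(inherits(ct, "ct_volume"), inherits(total, "mask_volume"))
  check_same_grid(total, ct, "total-lung mask")
  hu <- ct$voxels
  sm <- box_mean3(hu, params$smoothing_kernel)
  raw_air <- hu <= params$air_hu_max
  core <- sm <= params$air_hu_max
  if (!any(core) || !any(raw_air)) {
    return(mask_volume(array(FALSE, dim = dim(hu)), ct$spacing))
  }
  lab <- label_components(raw_air, 6L)
  airway <- border_labels(lab, "z")               # trachea + exterior reach z faces
  core_labs <- unique(lab[core & lab > 0])
  keep <- setdiff(core_labs, airway)
  detected <- array(lab %in% keep, dim = dim(lab)) & total$voxels
  detected <- drop_small_components(detected, params$min_component_ml, ct$spacing)
  mask_volume(detected, ct$spacing)
}

#' Combine masks into a disjoint lung partition
#'
#' Enforces `normal` and `ptx` inside `total` by intersection, gives
#' pneumothorax precedence over the normal window where they overlap, and
#' defines contusion as the remainder: `total & !normal & !ptx`. The
#' result is an exact partition (pairwise disjoint, union = total).
#'
#' @param ct a [ct_volume()] (grid reference).
#' @param total,normal,ptx [mask_volume()]s on the CT grid.
#' @return A `lung_partition` with masks `total`, `normal`, `contusion`,
#'   `pneumothorax`.
#' @export
derive_partition <- function(ct, total, normal, ptx) {
  stopifnot(inherits(ct, "ct_volume"))
  for (m in list(total, normal, ptx)) check_same_grid(m, ct, "partition mask")
  t_ <- total$voxels
  p_ <- ptx$voxels & t_
  n_ <- normal$voxels & t_ & !p_
  c_ <- t_ & !n_ & !p_
  lung_partition(
    total = mask_volume(t_, ct$spacing),
    normal = mask_volume(n_, ct$spacing),
    contusion = mask_volume(c_, ct$spacing),
    pneumothorax = mask_volume(p_, ct$spacing)
  )
}

#' Lung partition container
#'
#' Validates on construction that the three class masks are pairwise
#' disjoint and union exactly to the total mask.
#'
#' @param total,normal,contusion,pneumothorax [mask_volume()]s on one grid.
#' @return A `lung_partition` list.
#' @export
lung_partition <- function(total, normal, contusion, pneumothorax) {
  masks <- list(total = total, normal = normal, contusion = contusion,
                pneumothorax = pneumothorax)
  for (m in masks[-1]) check_same_grid(m, total, "partition mask")
  n_ <- normal$voxels; c_ <- contusion$voxels; p_ <- pneumothorax$voxels
  if (any(n_ & c_) || any(n_ & p_) || any(c_ & p_))
    cv_stop("cv_geometry_error", "partition masks are not pairwise disjoint")
  if (!identical(n_ | c_ | p_, total$voxels))
    cv_stop("cv_geometry_error", "partition masks do not union to the total mask")
  structure(c(masks, list(spacing = total$spacing)), class = "lung_partition")
}

#' End-to-end segmentation of one CT
#'
#' Total-lung surrogate (or an externally supplied mask), normal-lung HU
#' window, pneumothorax search, and partition derivation in one call.
#'
#' @param ct a [ct_volume()].
#' @param params a [seg_params()].
#' @param total_mask optional externally produced total-lung
#'   [mask_volume()] accepted verbatim (mirrors using a learned
#'   segmentation as given).
#' @return A [lung_partition()].
#' @export
segment_ct <- function(ct, params = seg_params(), total_mask = NULL) {
  total <- if (is.null(total_mask)) segment_total_lung(ct, params) else {
    check_same_grid(total_mask, ct, "external total mask")
    total_mask
  }
  normal <- segment_normal_lung(ct, total, params)
  ptx <- detect_pneumothorax(ct, total, params)
  derive_partition(ct, total, normal, ptx)
}

#' @export
print.lung_partition <- function(x, ...) {
  v <- vapply(x[c("total", "normal", "contusion", "pneumothorax")],
              mask_volume_ml, numeric(1))
  cat(sprintf("lung_partition: total %.1f mL | normal %.1f | contusion %.1f | pneumothorax %.1f\n",
              v[1], v[2], v[3], v[4]))
  invisible(x)
}
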