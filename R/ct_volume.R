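#' CT volume container
#'
#' A 3D grid of Hounsfield-unit (HU) values with physical voxel spacing.
#' Axis order is fixed as (z, y, x) and spacing is `(dz, dy, dx)` in mm.
#' Values outside the plausible HU range (-1100, 4000) are rejected: stored
#' DICOM values that were never rescaled to HU would otherwise propagate as
#' a silent unit error.
#'
#' @param voxels 3D numeric array of HU values, dim = (nz, ny, nx).
#' @param spacing numeric length-3, `(dz, dy, dx)` in mm, all > 0.
#' @return An object of class `ct_volume` with elements `voxels` and
#'   `spacing`.
#' @examples
#' ct <- ct_volume(array(-750, dim = c(4, 8, 8)), spacing = c(2.5, 1, 1))
#' voxel_volume_ml(ct)
#' @export
ct_volume <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cv_stop("cv_format_error", "voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    cv_stop("cv_geometry_error",
            "spacing must be three strictly positive finite values (dz, dy, dx)")
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels)))
    cv_stop("cv_format_error", "HU values must all be finite")
  rng <- range(voxels)
  if (rng[1] < -1100 || rng[2] > 4000)
    cv_stop("cv_format_error",
            "values outside (-1100, 4000) HU: volume looks non-HU-calibrated (range %.1f..%.1f)",
            rng[1], rng[2])
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' Binary mask on a CT grid
#'
#' @param voxels 3D logical array, dim = (nz, ny, nx).
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    cv_stop("cv_format_error", "mask voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    cv_stop("cv_geometry_error", "spacing must be three strictly positive values")
  if (!is.logical(voxels)) {
    voxels <- array(as.numeric(voxels) > 0.5, dim = dim(voxels))
  }
  if (anyNA(voxels))
    cv_stop("cv_format_error", "mask contains NA")
  structure(list(voxels = voxels, spacing = spacing), class = "mask_volume")
}

#' Volume of one voxel in millilitres
#'
#' @param x a `ct_volume` or `mask_volume`.
#' @return `dz * dy * dx / 1000` in mL.
#' @export
voxel_volume_ml <- function(x) {
  stopifnot(inherits(x, c("ct_volume", "mask_volume")))
  prod(x$spacing) / 1000
}

# Enforce that a mask annotates the same grid as a reference volume.
check_same_grid <- function(mask, reference, what = "mask") {
  if (!identical(dim(mask$voxels), dim(reference$voxels)))
    cv_stop("cv_geometry_error",
            "%s shape (%s) does not match reference grid (%s)", what,
            paste(dim(mask$voxels), collapse = "x"),
            paste(dim(reference$voxels), collapse = "x"))
  if (max(abs(mask$spacing - reference$spacing)) > 1e-6 * max(reference$spacing))
    cv_stop("cv_geometry_error", "%s spacing does not match reference spacing", what)
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], voxel volume %.4g mL\n",
              min(x$voxels), max(x$voxels), voxel_volume_ml(x)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("mask_volume: %d x %d x %d voxels, %d set (%.2f mL)\n",
              d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * voxel_volume_ml(x)))
  invisible(x)
}
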