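#' Load a CT volume
#'
#' Reads a chest CT either from a single NIfTI-1 file (`.nii` / `.nii.gz`)
#' or from a directory holding one DICOM series (uncompressed little-endian
#' CT slices). DICOM stored values are converted to Hounsfield units with
#' the per-file rescale slope/intercept and slices are sorted by their
#' position along the slice normal; inter-slice spacing must be uniform to
#' within 1%.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"auto"` (default, decided by whether `path` is a
#'   directory), `"nifti"` or `"dicom_dir"`.
#' @return A [ct_volume()].
#' @export
load_ct <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path))
      cv_stop("cv_io_error", "file not found: %s", path)
    r <- read_nifti(path)
  } else {
    if (!dir.exists(path))
      cv_stop("cv_io_error", "directory not found: %s", path)
    r <- read_dicom_dir(path)
  }
  ct_volume(r$voxels, r$spacing)
}

#' Save a CT volume as NIfTI-1
#'
#' HU values are written as 32-bit floats (little-endian, diagonal sform);
#' `.gz` suffix triggers gzip compression.
#'
#' @param vol a [ct_volume()].
#' @param path destination `.nii` or `.nii.gz`.
#' @export
save_ct <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    cv_stop("cv_io_error", "directory not writable or missing: %s", dir)
  write_nifti(vol$voxels, vol$spacing, path, datatype = "float32")
  invisible(path)
}

#' Save a mask as NIfTI-1 (unsigned 8-bit 0/1)
#'
#' @param mask a [mask_volume()].
#' @param path destination `.nii` or `.nii.gz`.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    cv_stop("cv_io_error", "directory not writable or missing: %s", dir)
  write_nifti(array(as.integer(mask$voxels), dim = dim(mask$voxels)),
              mask$spacing, path, datatype = "uint8")
  invisible(path)
}

#' Load a mask and check it against a reference grid
#'
#' Values are binarized at 0.5 (external masks are often stored as float
#' probabilities or 0/255 labels). Shape and spacing must match the
#' reference CT exactly.
#'
#' @param path NIfTI file.
#' @param reference the [ct_volume()] the mask annotates.
#' @return A [mask_volume()] on the reference grid.
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  if (!file.exists(path))
    cv_stop("cv_io_error", "file not found: %s", path)
  r <- read_nifti(path)
  m <- mask_volume(r$voxels > 0.5, r$spacing)
  check_same_grid(m, reference, what = basename(path))
  m
}
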