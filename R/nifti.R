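# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# No R NIfTI package is assumed. Supported subset: single-file NIfTI-1
# ("n+1" magic), 3D images, little- or big-endian headers, data types
# uint8 / int8 / int16 / uint16 / int32 / float32 / float64, scl_slope /
# scl_inter rescaling, arbitrary vox_offset. Written files are always
# little-endian with a diagonal sform. On disk the x index is fastest
# (the NIfTI convention); in memory the package uses (z, y, x), so data
# are permuted on the way in and out.

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_nifti <- function(path) {
  if (!file.exists(path))
    cv_stop("cv_io_error", "file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L)
    cv_stop("cv_io_error", "truncated NIfTI header in %s", path)
  rd <- function(off, what, n, size, endian, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, "little") != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, "big") != 348L)
      cv_stop("cv_format_error", "%s is not a NIfTI-1 file (bad sizeof_hdr)", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    cv_stop("cv_format_error", "%s is not a NIfTI-1 file (magic '%s')", path, magic)
  if (magic == "ni1")
    cv_stop("cv_format_error", "two-file NIfTI (.hdr/.img) is not supported")
  dims <- rd(40L, "integer", 8L, 2L, endian)
  ndim <- dims[1]
  if (ndim < 3L)
    cv_stop("cv_format_error", "only 3D NIfTI volumes are supported")
  if (ndim > 3L && any(dims[seq(5L, 1L + ndim)] > 1L))
    cv_stop("cv_format_error", "only 3D NIfTI volumes are supported (dim = %s)",
            paste(dims[2:(1 + ndim)], collapse = "x"))
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    cv_stop("cv_format_error", "unsupported NIfTI datatype code %d", datatype)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- as.double(nx) * ny * nz
  v <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
               signed = dt$signed)
  if (length(v) < n)
    cv_stop("cv_io_error", "truncated NIfTI data in %s", path)
  v <- as.double(v)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr_xyz <- array(v, dim = c(nx, ny, nz))
  list(
    voxels = aperm(arr_xyz, c(3, 2, 1)),           # -> (z, y, x)
    spacing = c(abs(pixdim[4]), abs(pixdim[3]), abs(pixdim[2]))
  )
}

write_nifti <- function(voxels, spacing, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  d <- dim(voxels)                                  # (nz, ny, nx)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  dz <- spacing[1]; dy <- spacing[2]; dx <- spacing[3]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    if (length(b) > 0) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  dtcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  wi(348L, 4L)                       # sizeof_hdr
  wc("", 10L); wc("", 18L)           # data_type, db_name (unused)
  wi(0L, 4L); wi(0L, 2L)             # extents, session_error
  writeBin(charToRaw("r"), con)      # regular
  writeBin(as.raw(0L), con)          # dim_info
  wi(c(3L, nx, ny, nz, 1L, 1L, 1L, 1L), 2L)          # dim
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent_p1..p3, intent_code
  wi(dtcode, 2L); wi(bitpix, 2L); wi(0L, 2L)          # datatype, bitpix, slice_start
  wf(c(1, dx, dy, dz, 0, 0, 0, 0))   # pixdim (qfac = 1)
  wf(352); wf(1); wf(0)              # vox_offset, scl_slope, scl_inter
  wi(0L, 2L)                         # slice_end
  writeBin(as.raw(c(0L, 2L)), con)   # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wc("contuvol", 80L); wc("", 24L)   # descrip, aux_file
  wi(c(0L, 1L), 2L)                  # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))     # quatern, qoffset
  wf(c(dx, 0, 0, 0))                 # srow_x
  wf(c(0, dy, 0, 0))                 # srow_y
  wf(c(0, 0, dz, 0))                 # srow_z
  wc("", 16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4L), con)             # extension flag: none
  arr_xyz <- aperm(voxels, c(3, 2, 1))
  if (datatype == "float32") {
    writeBin(as.double(arr_xyz), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(arr_xyz), con, size = 1L, endian = "little")
  }
  invisible(path)
}
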