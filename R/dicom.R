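# Minimal DICOM Part-10 reader for uncompressed CT series.
#
# Supported subset: little-endian explicit or implicit VR transfer syntaxes
# (1.2.840.10008.1.2.1 / 1.2.840.10008.1.2), monochrome 16-bit pixel data,
# no sequences inside the tags the reader needs, no compressed syntaxes.
# That covers what a thin-client CT volumetry pipeline requires; anything
# else raises a format error rather than guessing.

dicom_tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

# String value with trailing NUL/space padding stripped.
dicom_string <- function(bytes) {
  bytes <- bytes[bytes != as.raw(0L)]
  sub("\\s+$", "", rawToChar(bytes))
}

# Parse one file; returns header fields + a [y, x] HU matrix.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    cv_stop("cv_format_error", "%s is not a DICOM Part-10 file", path)
  pos <- 133L   # 1-based offset of the next byte to read
  n <- length(raw)
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4L,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  transfer_syntax <- "1.2.840.10008.1.2.1"
  implicit_body <- FALSE
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    in_meta <- group == 2L
    implicit <- !in_meta && implicit_body
    if (implicit) {
      len <- u32(pos + 4L)
      vr <- "UN"
      hdr_len <- 8L
    } else {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        hdr_len <- 12L
      } else {
        len <- u16(pos + 6L)
        hdr_len <- 8L
      }
    }
    if (len < 0L)
      cv_stop("cv_format_error", "undefined-length element in %s not supported", path)
    val_at <- pos + hdr_len
    if (val_at + len - 1L > n)
      cv_stop("cv_io_error", "truncated DICOM element in %s", path)
    key <- dicom_tag_key(group, element)
    keep <- key %in% c("0002,0010", "0008,0060", "0018,0050", "0020,0032",
                       "0020,0037", "0028,0010", "0028,0011", "0028,0030",
                       "0028,0100", "0028,0103", "0028,1052", "0028,1053",
                       "7fe0,0010")
    if (keep) {
      bytes <- if (len > 0L) raw[val_at:(val_at + len - 1L)] else raw(0L)
      tags[[key]] <- list(vr = vr, bytes = bytes)
    }
    if (key == "0002,0010") {
      transfer_syntax <- dicom_string(tags[[key]]$bytes)
      if (transfer_syntax == "1.2.840.10008.1.2") {
        implicit_body <- TRUE
      } else if (transfer_syntax != "1.2.840.10008.1.2.1") {
        cv_stop("cv_format_error",
                "unsupported DICOM transfer syntax %s in %s", transfer_syntax, path)
      }
    }
    pos <- val_at + len
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    dicom_string(t$bytes)
  }
  getds <- function(key) {
    s <- getstr(key)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getus <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$bytes, "integer", size = 2L, endian = "little", signed = FALSE)
  }
  modality <- getstr("0008,0060")
  if (is.null(modality) || modality != "CT")
    cv_stop("cv_format_error", "%s: modality '%s' is not CT", path,
            if (is.null(modality)) "<missing>" else modality)
  rows <- getus("0028,0010"); cols <- getus("0028,0011")
  bits <- getus("0028,0100")
  pixrep <- getus("0028,0103")
  slope <- getds("0028,1053"); inter <- getds("0028,1052")
  if (is.null(slope) || is.null(inter))
    cv_stop("cv_format_error",
            "%s: missing rescale slope/intercept; cannot convert to HU", path)
  if (is.null(bits) || bits != 16L)
    cv_stop("cv_format_error", "%s: only 16-bit pixel data supported", path)
  pix <- tags[["7fe0,0010"]]
  if (is.null(pix))
    cv_stop("cv_format_error", "%s: no pixel data", path)
  stored <- readBin(pix$bytes, "integer", n = rows * cols, size = 2L,
                    endian = "little",
                    signed = !is.null(pixrep) && pixrep == 1L)
  hu <- slope[1] * stored + inter[1]
  # pixel order is row-major (x fastest); build a [y, x] matrix
  slice <- t(matrix(hu, nrow = cols, ncol = rows))
  list(
    slice = slice,
    position = getds("0020,0032"),
    orientation = getds("0020,0037"),
    pixel_spacing = getds("0028,0030"),   # (row spacing dy, column spacing dx)
    slice_thickness = getds("0018,0050")
  )
}

# Read a directory of DICOM slices into (voxels, spacing), slices sorted by
# position along the slice normal.
read_dicom_dir <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    cv_stop("cv_io_error", "no files in DICOM directory %s", path)
  slices <- lapply(sort(files), read_dicom_file)
  ps <- t(vapply(slices, function(s) {
    if (is.null(s$pixel_spacing) || length(s$pixel_spacing) != 2L)
      cv_stop("cv_format_error", "slice without PixelSpacing in %s", path)
    s$pixel_spacing
  }, numeric(2)))
  if (any(abs(sweep(ps, 2, ps[1, ])) > 1e-4 * max(ps)))
    cv_stop("cv_geometry_error", "in-plane spacing differs across slices in %s", path)
  ors <- lapply(slices, function(s) s$orientation)
  if (!is.null(ors[[1]])) {
    for (o in ors) {
      if (is.null(o) || max(abs(o - ors[[1]])) > 1e-4)
        cv_stop("cv_geometry_error", "slice orientation differs across slices in %s", path)
    }
  }
  dims <- vapply(slices, function(s) dim(s$slice), numeric(2))
  if (any(dims != dims[, 1]))
    cv_stop("cv_geometry_error", "slice dimensions differ across slices in %s", path)
  nz <- length(slices)
  if (nz > 1L) {
    # normal = cross product of the two orientation rows (default axial)
    o <- if (is.null(ors[[1]])) c(1, 0, 0, 0, 1, 0) else ors[[1]]
    r <- o[1:3]; c_ <- o[4:6]
    nrm <- c(r[2] * c_[3] - r[3] * c_[2],
             r[3] * c_[1] - r[1] * c_[3],
             r[1] * c_[2] - r[2] * c_[1])
    z <- vapply(slices, function(s) {
      if (is.null(s$position))
        cv_stop("cv_format_error", "multi-slice series without ImagePositionPatient")
      sum(s$position * nrm)
    }, numeric(1))
    ord <- order(z)
    slices <- slices[ord]
    z <- z[ord]
    dz_all <- diff(z)
    if (any(dz_all <= 0))
      cv_stop("cv_geometry_error", "duplicate slice positions in %s", path)
    dz <- stats::median(dz_all)
    if (max(abs(dz_all - dz)) > 0.01 * dz)
      cv_stop("cv_geometry_error",
              "slice spacing varies by more than 1%% in %s", path)
  } else {
    dz <- if (!is.null(slices[[1]]$slice_thickness)) slices[[1]]$slice_thickness[1] else 1
  }
  d <- dim(slices[[1]]$slice)
  vox <- array(0, dim = c(nz, d[1], d[2]))
  for (i in seq_len(nz)) vox[i, , ] <- slices[[i]]$slice
  list(voxels = vox, spacing = c(dz, ps[1, 1], ps[1, 2]))
}
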