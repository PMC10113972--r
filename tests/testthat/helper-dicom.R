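# Test-only writer of synthetic DICOM CT slices (explicit VR little endian,
# Part-10). DICOM *writing* is out of scope for the package API; this helper
# exists solely to create fixtures for the reader at test time.

write_dicom_element <- function(con, group, element, vr, bytes) {
  writeBin(as.integer(c(group, element)), con, size = 2L, endian = "little")
  writeChar(vr, con, nchars = 2L, eos = NULL)
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    writeBin(as.integer(c(0L)), con, size = 2L, endian = "little")
    writeBin(length(bytes), con, size = 4L, endian = "little")
  } else {
    writeBin(length(bytes), con, size = 2L, endian = "little")
  }
  if (length(bytes) > 0) writeBin(bytes, con)
}

dicom_str_bytes <- function(s) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))   # even length padding
  b
}

dicom_us_bytes <- function(x) {
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

# Write one slice; `stored` is a [y, x] matrix of stored (pre-rescale)
# integer values; HU = slope * stored + intercept.
write_dicom_slice <- function(path, stored, spacing_yx, z_mm,
                              slope = 1, intercept = -1024,
                              modality = "CT",
                              transfer_syntax = "1.2.840.10008.1.2.1") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  ts_bytes <- dicom_str_bytes(transfer_syntax)
  # file meta group: group length + transfer syntax UID
  write_dicom_element(con, 0x0002L, 0x0000L, "UL",
                      writeBin(8L + length(ts_bytes), raw(), size = 4L,
                               endian = "little"))
  write_dicom_element(con, 0x0002L, 0x0010L, "UI", ts_bytes)
  implicit <- transfer_syntax == "1.2.840.10008.1.2"
  emit <- function(group, element, vr, bytes) {
    if (implicit) {
      writeBin(as.integer(c(group, element)), con, size = 2L, endian = "little")
      writeBin(length(bytes), con, size = 4L, endian = "little")
      if (length(bytes) > 0) writeBin(bytes, con)
    } else {
      write_dicom_element(con, group, element, vr, bytes)
    }
  }
  emit(0x0008L, 0x0060L, "CS", dicom_str_bytes(modality))
  emit(0x0018L, 0x0050L, "DS", dicom_str_bytes("2.5"))
  emit(0x0020L, 0x0032L, "DS",
       dicom_str_bytes(sprintf("0\\0\\%g", z_mm)))
  emit(0x0020L, 0x0037L, "DS", dicom_str_bytes("1\\0\\0\\0\\1\\0"))
  emit(0x0028L, 0x0010L, "US", dicom_us_bytes(nrow(stored)))
  emit(0x0028L, 0x0011L, "US", dicom_us_bytes(ncol(stored)))
  emit(0x0028L, 0x0030L, "DS",
       dicom_str_bytes(sprintf("%g\\%g", spacing_yx[1], spacing_yx[2])))
  emit(0x0028L, 0x0100L, "US", dicom_us_bytes(16L))
  emit(0x0028L, 0x0103L, "US", dicom_us_bytes(1L))   # signed
  emit(0x0028L, 0x1052L, "DS", dicom_str_bytes(sprintf("%g", intercept)))
  emit(0x0028L, 0x1053L, "DS", dicom_str_bytes(sprintf("%g", slope)))
  # pixel data, row-major (x fastest): transpose the [y, x] matrix
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  emit(0x7FE0L, 0x0010L, "OW", pix)
  invisible(path)
}

# Write a whole series from a (z, y, x) array of *stored* values.
write_dicom_series <- function(dir, stored_zyx, spacing = c(2.5, 1.5, 1.5),
                               slope = 1, intercept = -1024, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(stored_zyx)[1]
  for (i in seq_len(nz)) {
    write_dicom_slice(
      file.path(dir, sprintf("slice_%03d.dcm", i)),
      stored_zyx[i, , ], spacing_yx = spacing[2:3],
      z_mm = (i - 1) * spacing[1],
      slope = slope, intercept = intercept, ...
    )
  }
  invisible(dir)
}
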