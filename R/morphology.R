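# R-side wrappers around the compiled 3D primitives. All operate on plain
# logical/numeric arrays in (z, y, x) order; spacing-aware helpers take the
# (dz, dy, dx) spacing so structuring elements are isotropic in mm.

box_mean3 <- function(vol, k) {
  d <- dim(vol)
  out <- cpp_box_mean3(as.numeric(vol), as.integer(d), as.integer(k))
  array(out, dim = d)
}

label_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  array(cpp_label3(as.logical(mask), as.integer(d), as.integer(connectivity)),
        dim = d)
}

# Ellipsoidal (ball in mm) structuring element as integer voxel offsets.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(radius_mm / spacing, 0)
  lim <- pmax(floor(r), 0)
  g <- expand.grid(d1 = -lim[1]:lim[1], d2 = -lim[2]:lim[2], d3 = -lim[3]:lim[3])
  term <- function(d, ri) {
    if (ri > 0) (d / ri)^2 else ifelse(d == 0, 0, Inf)
  }
  keep <- term(g$d1, r[1]) + term(g$d2, r[2]) + term(g$d3, r[3]) <= 1
  as.matrix(g[keep, , drop = FALSE])
}

binary_dilate <- function(mask, offsets) {
  d <- dim(mask)
  array(cpp_dilate3(as.logical(mask), as.integer(d),
                    matrix(as.integer(offsets), ncol = 3)), dim = d)
}

# Erosion as complement-dilation with the (symmetric) structuring element.
binary_erode <- function(mask, offsets) {
  !binary_dilate(!mask, offsets)
}

binary_close <- function(mask, radius_mm, spacing) {
  off <- ball_offsets(radius_mm, spacing)
  binary_erode(binary_dilate(mask, off), off)
}

# Fill 3D holes: complement components that do not touch the volume border
# are interior cavities and get filled.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 6L)
  border <- unique(c(lab[1, , ], lab[dim(lab)[1], , ],
                     lab[, 1, ], lab[, dim(lab)[2], ],
                     lab[, , 1], lab[, , dim(lab)[3]]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

# Drop connected components smaller than min_ml millilitres.
drop_small_components <- function(mask, min_ml, spacing, connectivity = 6L) {
  if (min_ml <= 0 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  vox_ml <- prod(spacing) / 1000
  keep <- which(sizes * vox_ml >= min_ml)
  mask & array(lab %in% keep, dim = dim(mask))
}
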