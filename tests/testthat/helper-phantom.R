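# Shared fixtures: phantoms are generated once per test run and cached,
# since several test files reuse the same configurations. The "full" grid
# (96 x 128 x 128) is used where accuracy targets are asserted; the small
# grid (64 x 96 x 96) keeps property sweeps fast.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(fraction, ptx = 0, seed = 3,
                           shape = c(64L, 96L, 96L), ...) {
  key <- paste(fraction, ptx, seed, paste(shape, collapse = "x"), sep = "|")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(phantom_config(
      shape = shape,
      target_contusion_fraction = fraction,
      pneumothorax_fraction = ptx,
      seed = seed, ...
    ))
  }
  .phantom_cache[[key]]
}

full_grid <- c(96L, 128L, 128L)

dice_coef <- function(a, b) {
  if (inherits(a, "mask_volume")) a <- a$voxels
  if (inherits(b, "mask_volume")) b <- b$voxels
  2 * sum(a & b) / (sum(a) + sum(b))
}

truth_partition <- function(ph) {
  derive_partition(ph$ct, ph$total_lung, ph$normal_lung, ph$pneumothorax)
}
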