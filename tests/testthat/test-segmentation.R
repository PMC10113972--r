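test_that("3D box mean filter matches a brute-force window loop", {
  set.seed(21)
  v <- array(rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  got <- contuvol:::box_mean3(v, 3L)
  oracle <- array(NA_real_, dim = dim(v))
  for (i in 1:6) for (j in 1:7) for (k in 1:8) {
    ii <- max(1, i - 1):min(6, i + 1)
    jj <- max(1, j - 1):min(7, j + 1)
    kk <- max(1, k - 1):min(8, k + 1)
    oracle[i, j, k] <- mean(v[ii, jj, kk])
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_identical(contuvol:::box_mean3(v, 1L), v)
})

test_that("total-lung surrogate recovers the truth lung field", {
  ph0 <- cached_phantom(0, seed = 11, shape = full_grid)
  total0 <- segment_total_lung(ph0$ct)
  expect_gte(dice_coef(total0, ph0$total_lung), 0.95)
  ph40 <- cached_phantom(40, seed = 8, shape = full_grid)
  total40 <- segment_total_lung(ph40$ct)
  expect_gte(dice_coef(total40, ph40$total_lung), 0.90)
  # consolidation cores (HU > -100, i.e. outside the lung-candidate window)
  # are pulled back in by closing + hole filling; cores that breach the
  # pleural surface can stay open, so coverage is majority, not total
  consol <- ph40$contusion$voxels & ph40$ct$voxels > -100
  expect_gt(sum(consol), 0)
  expect_gt(sum(consol & total40$voxels) / sum(consol), 0.5)
})

test_that("a volume with no air fails segmentation cleanly", {
  ct <- ct_volume(array(40, dim = c(32, 64, 64)), c(2.5, 1.5, 1.5))
  expect_error(segment_total_lung(ct), class = "cv_segmentation_error")
})

test_that("normal-lung window is inclusive, monotone, and accurate on phantoms", {
  sp <- c(2, 2, 2)
  hu <- array(-700, dim = c(8, 8, 8))
  hu[1, 1, 1] <- -950; hu[1, 1, 2] <- -450       # exact bounds included
  hu[2, , ] <- -1000                              # below the window
  ct <- ct_volume(hu, sp)
  total <- mask_volume(array(TRUE, dim = dim(hu)), sp)
  norm <- segment_normal_lung(ct, total, seg_params(min_component_ml = 0))
  expect_true(norm$voxels[1, 1, 1] && norm$voxels[1, 1, 2])
  expect_false(any(norm$voxels[2, , ]))
  expect_true(all(norm$voxels[3:8, , ]))
  # uniform -1000 cube -> empty
  ct2 <- ct_volume(array(-1000, dim = c(8, 8, 8)), sp)
  expect_equal(sum(segment_normal_lung(ct2, total, seg_params())$voxels), 0)
  # widening the window never shrinks the mask
  ph <- cached_phantom(25, ptx = 10, seed = 3)
  tot <- segment_total_lung(ph$ct)
  narrow <- segment_normal_lung(ph$ct, tot, seg_params())
  wide <- segment_normal_lung(ph$ct, tot,
                              seg_params(normal_hu_window = c(-980, -300)))
  expect_true(all(!narrow$voxels | wide$voxels))
  # accuracy against truth
  ph_full <- cached_phantom(25, ptx = 10, seed = 3, shape = full_grid)
  tot_full <- segment_total_lung(ph_full$ct)
  nrm <- segment_normal_lung(ph_full$ct, tot_full)
  expect_gte(dice_coef(nrm, ph_full$normal_lung), 0.95)
})

test_that("pneumothorax detection finds pure-air pockets and ignores alveoli", {
  # aerated lung only: no voxel survives the mean filter below -950
  ph0 <- cached_phantom(0, seed = 11, shape = full_grid)
  tot <- segment_total_lung(ph0$ct)
  ptx <- detect_pneumothorax(ph0$ct, tot, seg_params(min_component_ml = 0))
  expect_equal(sum(ptx$voxels), 0)
  # ~30 mL pleural crescent (2.6% of a ~1150 mL lung): volume within 10%
  ph <- generate_phantom(phantom_config(shape = full_grid,
                                        target_contusion_fraction = 15,
                                        pneumothorax_fraction = 2.6, seed = 7))
  truth_ml <- mask_volume_ml(ph$pneumothorax)
  expect_gt(truth_ml, 25); expect_lt(truth_ml, 35)
  tot <- segment_total_lung(ph$ct)
  det <- detect_pneumothorax(ph$ct, tot)
  expect_lt(abs(mask_volume_ml(det) - truth_ml) / truth_ml, 0.10)
})

test_that("kernel = 1 false-positives on untruncated aerated lung; kernel 5 does not", {
  # the aerated HU model is truncated by default; lift the truncation so the
  # N(-750, 60) tail below -950 exists, as in real (noisy) parenchyma
  hu_model <- default_hu_model()
  hu_model$aerated_lung["lo"] <- -1060
  ph <- generate_phantom(phantom_config(shape = c(64L, 96L, 96L),
                                        target_contusion_fraction = 0,
                                        hu_model = hu_model, seed = 13))
  expect_gt(sum(ph$ct$voxels[ph$total_lung$voxels] <= -950), 0)
  tot <- segment_total_lung(ph$ct)
  p1 <- suppressWarnings(
    detect_pneumothorax(ph$ct, tot, seg_params(smoothing_kernel = 1,
                                               min_component_ml = 0)))
  expect_gt(sum(p1$voxels), 0)          # degenerate kernel: alveolar noise leaks
  p5 <- detect_pneumothorax(ph$ct, tot, seg_params(min_component_ml = 0))
  expect_equal(sum(p5$voxels), 0)       # default kernel suppresses it
})

test_that("pneumothorax detection is unaffected by adding contusion", {
  a <- cached_phantom(0, ptx = 6, seed = 9)
  b <- cached_phantom(15, ptx = 6, seed = 9)
  # same seed: the pleural pocket is the same voxel set in both phantoms
  expect_identical(a$pneumothorax$voxels, b$pneumothorax$voxels)
  da <- detect_pneumothorax(a$ct, a$total_lung)
  db <- detect_pneumothorax(b$ct, b$total_lung)
  expect_identical(da$voxels, a$pneumothorax$voxels)
  expect_identical(db$voxels, b$pneumothorax$voxels)
})

test_that("derive_partition produces an exact partition with ptx precedence", {
  ph <- cached_phantom(25, ptx = 10, seed = 3)
  part <- truth_partition(ph)
  expect_s3_class(part, "lung_partition")
  expect_identical(part$contusion$voxels, ph$contusion$voxels)
  # ptx empty -> contusion = total - normal
  ph2 <- cached_phantom(25, seed = 4)
  empty <- mask_volume(array(FALSE, dim = dim(ph2$ct$voxels)), ph2$ct$spacing)
  p2 <- derive_partition(ph2$ct, ph2$total_lung, ph2$normal_lung, empty)
  expect_identical(p2$contusion$voxels,
                   ph2$total_lung$voxels & !ph2$normal_lung$voxels)
  # normal = total -> contusion empty
  p3 <- derive_partition(ph2$ct, ph2$total_lung, ph2$total_lung, empty)
  expect_equal(sum(p3$contusion$voxels), 0)
  # geometry guards
  small <- mask_volume(array(TRUE, dim = c(4, 4, 4)), ph$ct$spacing)
  expect_error(derive_partition(ph$ct, ph$total_lung, small, empty),
               class = "cv_geometry_error")
  expect_error(
    lung_partition(ph$total_lung, ph$normal_lung, ph$normal_lung,
                   ph$pneumothorax),
    class = "cv_geometry_error"
  )
})

test_that("full pipeline recovers class masks and fraction on the phantom", {
  ph <- cached_phantom(25, ptx = 10, seed = 3, shape = full_grid)
  part <- segment_ct(ph$ct)
  expect_gte(dice_coef(part$total, ph$total_lung), 0.90)
  expect_gte(dice_coef(part$normal, ph$normal_lung), 0.90)
  expect_gte(dice_coef(part$contusion, ph$contusion), 0.90)
  expect_gte(dice_coef(part$pneumothorax, ph$pneumothorax), 0.90)
  # partition exactness of the estimated masks
  expect_identical(part$normal$voxels | part$contusion$voxels |
                     part$pneumothorax$voxels, part$total$voxels)
  # an externally supplied total mask is accepted verbatim
  part2 <- segment_ct(ph$ct, total_mask = ph$total_lung)
  expect_identical(part2$total$voxels, ph$total_lung$voxels)
})
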