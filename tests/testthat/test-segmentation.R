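test_that("iso-contour recovers a two-level phantom exactly", {
  tl <- two_level_volume()
  seg <- iso_contour_segment(tl$vol, 50)
  expect_identical(seg$n_voxels, tl$n_hot)
  expect_equal(seg$estimated_volume_mL, tl$n_hot * voxel_volume_mL(tl$grid))
  expect_equal(seg$total_counts, 1000 * tl$n_hot)
  expect_equal(seg$mean_counts_per_voxel, 1000)
  expect_equal(seg$reference_max, 1000)
})

test_that("threshold 100% keeps only the maximum's component", {
  tl <- two_level_volume()
  v <- tl$vol$values
  v[2, 2, 2] <- 2000  # isolated single hottest voxel
  vol <- activity_volume(v, tl$grid)
  seg <- iso_contour_segment(vol, 100)
  expect_identical(seg$n_voxels, 1L)
  expect_true(seg$mask[2, 2, 2])
})

test_that("segmentation statistics satisfy their defining identities", {
  tl <- two_level_volume()
  vol <- apply_system_blur(tl$vol, 6)
  for (t in c(25, 50, 80)) {
    seg <- iso_contour_segment(vol, t)
    expect_equal(seg$estimated_volume_mL,
                 seg$n_voxels * voxel_volume_mL(tl$grid))
    expect_equal(seg$total_counts, sum(vol$values[seg$mask]))
    expect_equal(seg$mean_counts_per_voxel, seg$total_counts / seg$n_voxels)
  }
})

test_that("mask equals exhaustive enumeration on small grids", {
  g <- grid_spec(c(24, 24, 24), 2)
  spec <- sphere_spec(20, c(24, 24, 24), 2, background_uCi_mL = 0.05)
  vol <- apply_system_blur(rasterize_phantom(spec, g, reference_model()), 7)
  for (t in c(30, 45, 60)) {
    seg <- iso_contour_segment(vol, t)
    oracle <- vol$values >= t / 100 * max(vol$values)  # single blob: no CC step
    expect_identical(seg$mask, oracle)
  }
})

test_that("largest connected component wins and empty masks are flagged", {
  g <- grid_spec(c(20, 20, 20), 2)
  v <- array(0, dim = g$shape)
  v[3:5, 3:5, 3:5] <- 800          # 27-voxel blob
  v[14:15, 14:15, 14:15] <- 1000   # 8-voxel hotter blob
  vol <- activity_volume(v, g)
  seg <- iso_contour_segment(vol, 50)
  expect_identical(seg$n_voxels, 27L)
  expect_false(seg$mask[14, 14, 14])

  # roi_box restricted to the hotter blob segments it alone
  seg2 <- iso_contour_segment(vol, 50, roi_box = list(lo = c(11, 11, 11),
                                                      hi = c(20, 20, 20)))
  expect_identical(seg2$n_voxels, 8L)
  expect_equal(seg2$reference_max, 1000)

  # the threshold is relative to the in-box maximum, so a valid threshold
  # always captures at least the argmax voxel
  v2 <- array(1, dim = g$shape); v2[10, 10, 10] <- 100
  vol2 <- activity_volume(v2, g)
  expect_false(iso_contour_segment(vol2, 100)$empty)
  expect_error(iso_contour_segment(vol2, 101), "threshold")
  zero <- activity_volume(array(0, dim = g$shape), g)
  expect_error(iso_contour_segment(zero, 50), "no signal")
  expect_error(iso_contour_segment(vol2, 50, roi_box = list(lo = c(0, 1, 1),
                                                            hi = g$shape)),
               "roi_box")
})

test_that("pre-component threshold masks are nested as threshold rises", {
  g <- grid_spec(c(24, 24, 24), 2)
  spec <- sphere_spec(15, c(24, 24, 24), 1)
  vol <- add_poisson_noise(
    apply_system_blur(rasterize_phantom(spec, g, reference_model()), 7), 2)
  cutmask <- function(t) vol$values >= t / 100 * max(vol$values)
  for (t in c(20, 30, 40, 50)) {
    expect_true(all(cutmask(t + 10) <= cutmask(t)))
  }
})

test_that("threshold sweep finds the exact-recovery plateau", {
  tl <- two_level_volume(hot = 1000, background = 100)
  sw <- threshold_sweep(tl$vol, tl$n_hot * voxel_volume_mL(tl$grid),
                        thresholds = seq(5, 100, by = 5))
  # every threshold strictly between 10% (background/max) and 100% is exact
  exact <- sw$sweep$abs_error_mL == 0
  expect_true(all(exact[sw$sweep$threshold_pct > 10 &
                          sw$sweep$threshold_pct <= 100]))
  # ties broken toward the lowest exact threshold
  expect_equal(sw$best_threshold, 15)
  expect_equal(sw$best_abs_error_mL, 0)
  expect_error(threshold_sweep(tl$vol, 0), "true_volume_mL")
  expect_error(threshold_sweep(tl$vol, 10, thresholds = numeric(0)),
               "thresholds")
})

test_that("estimated volume is non-increasing in threshold for a blurred sphere", {
  g <- grid_spec(c(32, 32, 32), 3)
  spec <- sphere_spec(50, c(48, 48, 48), 2)
  vol <- apply_system_blur(rasterize_phantom(spec, g, reference_model()), 8)
  sw <- threshold_sweep(vol, 50)
  expect_true(all(diff(sw$sweep$estimated_mL) <= 0))
})

test_that("standardization reports per-range thresholds and correlations", {
  g <- grid_spec(c(64, 64, 64), 5)
  ser <- generate_phantom_series(volumes_mL = c(6, 16, 30, 500, 1000, 1500,
                                                2400, 2800, 3200),
                                 grid = g, fwhm_mm = 0, noise = FALSE,
                                 seed = 1)
  std <- standardize_thresholds(ser)
  expect_identical(nrow(std), 3L)
  expect_true(all(std$best_threshold >= 19 & std$best_threshold <= 52))
  expect_true(all(std$n_phantoms == 3L))
  # noiseless two-level phantoms recover the voxelized volume exactly; the
  # residual decorrelation is pure voxelization error at this coarse grid
  expect_true(all(std$volume_correlation_r > 0.99))

  expect_error(standardize_thresholds(ser, ranges = list(c(1, 2))),
               "fewer than 2")
  expect_error(standardize_thresholds(list()), "empty")
})

test_that("connected-component labelling matches a hand-built case", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[1, 2, 1] <- TRUE   # face-adjacent to the first
  m[3, 3, 3] <- TRUE   # isolated
  m[4, 4, 4] <- TRUE   # diagonal to [3,3,3]: NOT 6-connected
  lab <- label_components(m)
  expect_identical(attr(lab, "n_components"), 3L)
  expect_identical(lab[1, 1, 1], lab[1, 2, 1])
  expect_false(lab[3, 3, 3] == lab[4, 4, 4])
  expect_identical(sum(lab > 0), 4L)
})
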