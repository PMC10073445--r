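test_that("rasterized sphere volume matches the analytic volume", {
  # 1 mL sphere (r = 6.2035 mm) at 1 mm isotropic spacing: ~1000 inside voxels
  g <- grid_spec(c(24, 24, 24), 1)
  spec <- sphere_spec(1, center_mm = c(12, 12, 12), concentration_uCi_mL = 1)
  vol <- rasterize_phantom(spec, g, identity_model())
  n_inside <- sum(vol$values > 0)
  expect_lt(abs(n_inside - 1000) / 1000, 0.04)

  # cylinder pi r^2 h: r = 50 mm, h = 127.324 mm -> 1000.0 mL; compare the
  # rasterization against an independent brute-force voxel-centre count
  g2 <- grid_spec(c(60, 60, 70), 2)
  cyl <- list(type = "cylinder", center_mm = c(60, 60, 70), radius_mm = 50,
              height_mm = 127.324)
  spec2 <- phantom_spec(cyl, concentration_uCi_mL = 1)
  expect_equal(spec2$true_volume_mL, pi * 50^2 * 127.324 / 1000,
               tolerance = 1e-9)
  vol2 <- rasterize_phantom(spec2, g2, identity_model())
  n_brute <- 0
  centres <- function(n, sp) (seq_len(n) - 0.5) * sp
  for (x in centres(60, 2)) for (y in centres(60, 2)) {
    if ((x - 60)^2 + (y - 60)^2 <= 50^2)
      n_brute <- n_brute + sum(abs(centres(70, 2) - 70) <= 127.324 / 2)
  }
  expect_identical(sum(vol2$values > 0), as.integer(n_brute))
  expect_lt(abs(n_brute * voxel_volume_mL(g2) - 1000) / 1000, 0.02)
})

test_that("rasterization handles degenerate contrast and geometry bounds", {
  g <- grid_spec(c(16, 16, 16), 2)
  flat <- phantom_spec(list(type = "sphere", center_mm = c(16, 16, 16),
                            radius_mm = 6),
                       concentration_uCi_mL = 2, background_uCi_mL = 2)
  vol <- rasterize_phantom(flat, g, identity_model())
  expect_equal(max(vol$values), min(vol$values))

  big <- phantom_spec(list(type = "sphere", center_mm = c(16, 16, 30),
                           radius_mm = 6), concentration_uCi_mL = 1)
  expect_error(rasterize_phantom(big, g, identity_model()), "axis z")
})

test_that("forward model puts the calibration line into voxel counts", {
  g <- grid_spec(c(16, 16, 16), 2)
  spec <- sphere_spec(4, c(16, 16, 16), concentration_uCi_mL = 2)
  vol <- rasterize_phantom(spec, g, reference_model())
  vox_cc <- voxel_volume_mL(g)
  expect_equal(max(vol$values), (6807.3 * 2 + 39.0) * vox_cc, tolerance = 1e-12)
  expect_equal(min(vol$values), 39.0 * vox_cc, tolerance = 1e-12)
})

test_that("system blur conserves counts and matches the Gaussian closed form", {
  g <- grid_spec(c(41, 41, 41), 1)
  v <- array(0, dim = g$shape)
  v[21, 21, 21] <- 1e6
  vol <- activity_volume(v, g)

  expect_identical(apply_system_blur(vol, 0)$values, vol$values)

  fwhm <- 10
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 4.2466, tolerance = 1e-4)
  b <- apply_system_blur(vol, fwhm)
  expect_equal(sum(b$values), sum(vol$values), tolerance = 1e-9)
  # axis profile ratios follow exp(-x^2 / (2 sigma^2)) exactly for a sampled
  # separable kernel
  prof <- b$values[21:29, 21, 21]
  expect_equal(prof / prof[1], exp(-(0:8)^2 / (2 * sigma^2)),
               tolerance = 1e-9)

  # constant volume is unchanged (reflection padding leaves no boundary dent)
  flat <- activity_volume(array(7, dim = g$shape), g)
  expect_equal(apply_system_blur(flat, 12)$values, flat$values,
               tolerance = 1e-9)

  expect_error(apply_system_blur(vol, -1), "fwhm")
})

test_that("Poisson noise is mean-preserving, seeded, and degenerate at zero", {
  g <- grid_spec(c(20, 25, 20), 2)
  zero <- activity_volume(array(0, dim = g$shape), g)
  expect_true(all(add_poisson_noise(zero, 5)$values == 0))

  vol <- activity_volume(array(10000, dim = g$shape), g)
  n1 <- add_poisson_noise(vol, 42)
  n2 <- add_poisson_noise(vol, 42)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_poisson_noise(vol, 43)$values))
  expect_lt(abs(mean(n1$values) - 10000) / 10000, 0.01)
})

test_that("phantom series covers requested volumes and is reproducible", {
  g <- grid_spec(c(32, 32, 32), 4)
  ser <- generate_phantom_series(volumes_mL = c(6, 16, 30),
                                 concentrations = 100, grid = g,
                                 fwhm_mm = 0, noise = FALSE, seed = 1)
  expect_length(ser, 3)
  expect_equal(vapply(ser, function(e) e$spec$true_volume_mL, numeric(1)),
               c(6, 16, 30), tolerance = 1e-9)
  # paper-range presets
  expect_equal(default_volume_ranges(),
               list(small = c(6, 30), medium = c(500, 1500),
                    large = c(2400, 3200)))
  expect_true(all(default_phantom_volumes() >= 6 &
                    default_phantom_volumes() <= 3200))

  ser_a <- generate_phantom_series(volumes_mL = 30, grid = g, fwhm_mm = 6,
                                   noise = TRUE, seed = 9)
  ser_b <- generate_phantom_series(volumes_mL = 30, grid = g, fwhm_mm = 6,
                                   noise = TRUE, seed = 9)
  expect_identical(ser_a[[1]]$vol$values, ser_b[[1]]$vol$values)
  expect_error(generate_phantom_series(volumes_mL = numeric(0)), "non-empty")
})

test_that("noiseless voxel values are monotone in object concentration", {
  g <- grid_spec(c(24, 24, 24), 3)
  prev <- NULL
  for (conc in c(0.5, 1, 2, 4)) {
    spec <- sphere_spec(8, c(36, 36, 36), conc, background_uCi_mL = 0.1)
    vol <- apply_system_blur(rasterize_phantom(spec, g, reference_model()), 8)
    if (!is.null(prev)) expect_true(all(vol$values >= prev - 1e-9))
    prev <- vol$values
  }
})

test_that("voxelization error shrinks as spacing is refined", {
  err_at <- function(sp) {
    g <- grid_spec(round(c(48, 48, 48) / sp), sp)
    spec <- sphere_spec(30, grid_extent_mm(g) / 2, 1)
    vol <- rasterize_phantom(spec, g, identity_model())
    abs(sum(vol$values > 0) * voxel_volume_mL(g) - 30)
  }
  expect_lt(err_at(1), err_at(4))
})
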