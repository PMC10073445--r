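test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(dose_record(148, 0)), 148)
  expect_equal(decay_correct(dose_record(148, 360.4)), 74)
  # closed-form cross-check: 2^(-t/T) == exp(-ln2 t / T)
  d <- dose_record(160, 30)
  expect_equal(decay_correct(d), 160 * exp(-log(2) * 30 / 360.4),
               tolerance = 1e-12)
  expect_equal(decay_correct(d) / 160, 0.9440, tolerance = 1e-4)
  expect_equal(decay_correct(d, correct = FALSE), 160)
  expect_error(dose_record(-1, 30), "positive")
  expect_error(dose_record(148, -5), ">= 0")
})

# build a uniform spherical "organ" carrying a known fraction of the dose
uniform_organ_fixture <- function(frac = 0.30, organ_mL = 1000,
                                  dose_MBq = 166.5, scan_min = 30) {
  g <- grid_spec(c(40, 40, 40), 4)
  dose <- dose_record(dose_MBq, scan_min)
  a_scan_uCi <- convert_activity(decay_correct(dose), "MBq", "uCi")
  conc <- frac * a_scan_uCi / organ_mL
  spec <- sphere_spec(organ_mL, grid_extent_mm(g) / 2, conc)
  vol <- rasterize_phantom(spec, g, reference_model())
  list(vol = vol, dose = dose, spec = spec, grid = g, conc = conc)
}

test_that("a uniform organ with 30% of the dose quantifies to %QLU 30", {
  fx <- uniform_organ_fixture()
  seg <- iso_contour_segment(fx$vol, 50)
  q <- organ_quant(seg, reference_model(), fx$dose, organ = "liver")
  # noiseless, unblurred: the voxelized volume replaces the analytic 1000 mL,
  # so %QLU = 30 * (voxel volume / analytic volume)
  expect_equal(q$pct_uptake, 30 * seg$estimated_volume_mL / 1000,
               tolerance = 1e-9)
  expect_lt(abs(q$pct_uptake - 30) / 30, 0.02)
  expect_equal(q$pct_id_per_mL * q$volume_mL, q$pct_uptake, tolerance = 1e-9)
  expect_equal(q$organ_activity_uCi / seg$estimated_volume_mL, fx$conc,
               tolerance = 1e-9)
})

test_that("a zero-concentration organ quantifies to zero uptake", {
  g <- grid_spec(c(16, 16, 16), 4)
  vox_cc <- voxel_volume_mL(g)
  # constant background at the calibration intercept: inverts to 0 everywhere
  vol <- activity_volume(array(39.0 * vox_cc, dim = g$shape), g)
  seg <- iso_contour_segment(vol, 50)
  q <- organ_quant(seg, reference_model(), dose_record(148, 30))
  expect_equal(q$pct_uptake, 0)
  expect_equal(q$pct_id_per_mL, 0)
})

test_that("uptake exceeding the injected dose is rejected as a unit fault", {
  fx <- uniform_organ_fixture(frac = 0.30)
  seg <- iso_contour_segment(fx$vol, 50)
  tiny_dose <- dose_record(1, 30)  # 1 MBq cannot hold 30% of 166 MBq
  expect_error(organ_quant(seg, reference_model(), tiny_dose),
               "exceeds injected dose")
})

test_that("the uptake identity holds across blurred noisy scans", {
  fx <- uniform_organ_fixture(frac = 0.22, organ_mL = 800)
  vol <- add_poisson_noise(apply_system_blur(fx$vol, 8), 3)
  for (t in c(30, 38, 45)) {
    q <- organ_quant(iso_contour_segment(vol, t), reference_model(), fx$dose)
    expect_equal(q$pct_id_per_mL * q$volume_mL, q$pct_uptake, tolerance = 1e-9)
    expect_gte(q$pct_uptake, 0)
  }
})

test_that("organ activities are additive over disjoint regions", {
  g <- grid_spec(c(40, 40, 20), 4)
  v <- array(39.0 * voxel_volume_mL(g), dim = g$shape)  # intercept background
  hotval <- (6807.3 * 2 + 39.0) * voxel_volume_mL(g)
  v[4:12, 4:12, 4:12] <- hotval          # "liver" block
  v[25:35, 25:35, 5:15] <- 0.6 * hotval  # "spleen" block
  vol <- activity_volume(v, g)
  dose <- dose_record(166.5, 30)
  m <- reference_model()
  liver <- organ_quant(iso_contour_segment(vol, 90,
             roi_box = list(lo = c(1, 1, 1), hi = c(16, 16, 16))), m, dose,
             organ = "liver")
  spleen <- organ_quant(iso_contour_segment(vol, 90,
             roi_box = list(lo = c(20, 20, 1), hi = c(40, 40, 20))), m, dose,
             organ = "spleen")
  # union oracle: direct sum over both blocks
  vox_cc <- voxel_volume_mL(g)
  conc_all <- counts_to_concentration(m, v / vox_cc, warn = FALSE)
  union_uCi <- sum(conc_all[4:12, 4:12, 4:12]) * vox_cc +
    sum(conc_all[25:35, 25:35, 5:15]) * vox_cc
  expect_equal(liver$organ_activity_uCi + spleen$organ_activity_uCi,
               union_uCi, tolerance = 1e-9)
})

test_that("paired visit deltas are follow-up minus baseline", {
  fx <- uniform_organ_fixture(frac = 0.30)
  seg <- iso_contour_segment(fx$vol, 50)
  base <- organ_quant(seg, reference_model(), fx$dose)
  expect_equal(unname(paired_visit_delta(base, base)), rep(0, 4))

  fx2 <- uniform_organ_fixture(frac = 0.45)
  fu <- organ_quant(iso_contour_segment(fx2$vol, 50), reference_model(),
                    fx2$dose)
  d <- paired_visit_delta(base, fu)
  expect_equal(d[["pct_uptake"]], fu$pct_uptake - base$pct_uptake)
  expect_equal(d[["pct_uptake"]], 15, tolerance = 0.1)
  expect_equal(d[["volume_mL"]], fu$volume_mL - base$volume_mL)

  spleen <- fu; spleen$organ <- "spleen"
  expect_error(paired_visit_delta(base, spleen), "organ mismatch")
})

test_that("end-to-end %QLU recovery under blur and noise is within 5%", {
  fx <- uniform_organ_fixture(frac = 0.30, organ_mL = 1200)
  vol <- add_poisson_noise(apply_system_blur(fx$vol, 8), 11)
  sw <- threshold_sweep(vol, 1200)
  q <- organ_quant(iso_contour_segment(vol, sw$best_threshold),
                   reference_model(), fx$dose, organ = "liver")
  expect_lt(abs(q$pct_uptake - 30) / 30, 0.05)
})
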