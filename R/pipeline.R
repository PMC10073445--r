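#' Run the full standardization-to-statistics workflow
#'
#' Executes the complete chain on synthetic data: (1) phantom threshold
#' standardization per volume range, (2) counts-to-concentration calibration
#' from phantoms spanning the concentration range, (3) a quantification
#' demonstration on a simulated liver scan with a known injected-dose
#' fraction, (4) cohort simulation, and (5) the severity/survival statistics
#' report. Every artifact embeds the seed and the configuration hash; a rerun
#' with the same configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the in-memory stage results and `files`,
#'   the paths written under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dig <- config_digest(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = config$seed, config_hash = dig$hash,
               package = as.character(utils::packageVersion("qspect")))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  grid <- grid_spec(config$grid_shape, config$grid_spacing)
  fwd <- calibration_model(6807.3, 39.0)
  files <- list()

  say("stage standardize: %d phantoms", length(config$phantom_volumes_mL))
  std <- stage("standardize", {
    series <- generate_phantom_series(
      volumes_mL = config$phantom_volumes_mL,
      concentrations = config$concentration_kBq_mL,
      grid = grid, forward_model = fwd, fwhm_mm = config$fwhm_mm,
      noise = config$noise, seed = config$seed)
    standardize_thresholds(series, ranges = config$ranges,
                           thresholds = config$thresholds)
  })
  files$standardization <- file.path(config$out_dir, "standardization.csv")
  write_csv_with_provenance(std, files$standardization, prov)

  say("stage calibrate: fitting counts/cc vs concentration")
  cal <- stage("calibrate", {
    conc_kBq <- seq(28.5, 151.33, length.out = 6)
    pts <- vapply(conc_kBq, function(ck) {
      ser <- generate_phantom_series(
        volumes_mL = 1000, concentrations = ck, grid = grid,
        forward_model = fwd, fwhm_mm = config$fwhm_mm, noise = config$noise,
        seed = config$seed + round(ck * 100))
      seg <- iso_contour_segment(ser[[1]]$vol, 38)
      seg$mean_counts_per_voxel / voxel_volume_mL(grid)
    }, numeric(1))
    fit_calibration(pts, convert_activity(conc_kBq, "kBq/mL", "uCi/mL"),
                    threshold_pct = 38)
  })
  files$calibration <- file.path(config$out_dir, "calibration.json")
  write_json_with_provenance(unclass(cal), files$calibration, prov)

  say("stage quant: simulated liver scan")
  quant <- stage("quant", {
    dose <- dose_record(166.5, injection_to_scan_min = 30)
    dose_uCi <- convert_activity(decay_correct(dose, config$decay_correction),
                                 "MBq", "uCi")
    target_frac <- 0.30
    liver_mL <- 1200
    spec <- sphere_spec(liver_mL, grid_extent_mm(grid) / 2,
                        target_frac * dose_uCi / liver_mL)
    vol <- rasterize_phantom(spec, grid, fwd)
    if (config$fwhm_mm > 0) vol <- apply_system_blur(vol, config$fwhm_mm)
    if (config$noise) vol <- add_poisson_noise(vol, config$seed + 104729L)
    best_t <- std$best_threshold[std$range_low_mL <= liver_mL &
                                   std$range_high_mL >= liver_mL][1]
    if (is.na(best_t)) best_t <- 38
    seg <- iso_contour_segment(vol, best_t)
    q <- organ_quant(seg, fwd, dose, organ = "liver",
                     decay_correction = config$decay_correction)
    c(unclass(q)[c("organ", "volume_mL", "organ_activity_uCi", "pct_uptake",
                   "pct_id_per_mL", "threshold_pct", "decay_corrected")],
      list(true_volume_mL = liver_mL, true_pct_uptake = 100 * target_frac))
  })
  files$quant <- file.path(config$out_dir, "quant.json")
  write_json_with_provenance(quant, files$quant, prov)

  say("stage cohort: n = %d (%s)", config$cohort_n, config$cohort_preset)
  cohort <- stage("cohort", {
    cfg <- scenario_presets(config$cohort_preset, n = config$cohort_n,
                            seed = config$seed)
    recode_outcomes(simulate_cohort(cfg))
  })
  files$cohort <- file.path(config$out_dir, "cohort.csv")
  write_cohort_csv(cohort, files$cohort,
                   provenance = list(config_hash = dig$hash))

  say("stage stats: severity strata, survival, Cox")
  report <- stage("stats", {
    sr <- severity_strata_report(cohort)
    km <- km_logrank(cohort$time_months, cohort$event, cohort$arm)
    cox <- cox_regression(
      data.frame(meld = cohort$meld, gcsf = as.integer(cohort$arm == "GCSF")),
      cohort$time_months, cohort$event)
    list(
      correlations = list(
        qlu_meld = pearson(cohort$qlu_pct, cohort$meld),
        qlu_ctp = pearson(cohort$qlu_pct, cohort$ctp_score),
        qlu_icg_r15 = pearson(cohort$qlu_pct, cohort$icg_r15)),
      anova_p = as.list(sr$anova_p),
      roc = lapply(sr$roc, function(d) lapply(d, function(r)
        r[c("auc", "cutoff", "sensitivity", "specificity", "ppv", "npv",
            "accuracy", "youden_j")])),
      survival = list(surv_12mo = as.list(survival_at(km, 12)),
                      logrank_p = km$logrank_p),
      cox = cox$coefficients)
  })
  files$report <- file.path(config$out_dir, "report.json")
  write_json_with_provenance(report, files$report, prov)

  manifest <- list(provenance = prov, config = dig$json,
                   files = lapply(files, basename))
  files$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(standardization = std, calibration = cal, quant = quant,
                 cohort = cohort, report = report, files = files,
                 provenance = prov))
}

write_csv_with_provenance <- function(df, path, prov) {
  hdr <- paste0("# qspect: ",
                paste(sprintf("%s=%s", names(prov), unlist(prov)),
                      collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

write_json_with_provenance <- function(x, path, prov) {
  jsonlite::write_json(c(list(provenance = prov), x), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
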