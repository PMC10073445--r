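# qspect

Quantitative Tc-99m sulfur colloid liver/spleen SPECT/CT analysis in R:
phantom-based threshold standardization, counts-to-concentration
calibration, organ uptake quantification, indocyanine green (ICG) kinetics,
and the prognostic statistics used to evaluate hepatic functional reserve in
decompensated cirrhosis. Everything runs on synthetic data — a digital
phantom simulator and a latent-severity cohort generator are part of the
package — so the full method is testable without scanners or patients.

It is written for nuclear-medicine physicists and hepatology researchers who
want a reproducible, end-to-end reference implementation of quantitative
liver SPECT ("Q-SPECT/CT") volumetry and uptake metrics.

## The method in brief

**Segmentation.** An organ or phantom insert is contoured at a fixed
threshold *t*% of the maximum voxel value in its analysis box, keeping the
largest 6-connected component. Volume is the mask voxel count times the
voxel volume. Phantom standardization sweeps *t* = 19–52% against inserts of
known volume and fixes, per volume range (6–30, 500–1500, 2400–3200 mL),
the threshold minimizing the summed absolute volume error.

**Calibration.** Reconstructed counts map to activity concentration through
an OLS line, `counts/cc = slope × uCi/cc + intercept` (reference
coefficients 6807.3 and 39.0).

**Quantification.** With injected activity A₀ decay-corrected to scan time
(A = A₀ · 2^(−t/360.4 min)), the percent quantitative liver uptake is

    %QLU = 100 · Σ_capture c_v · vox_cc / A,    %ID/mL = %QLU / volume

where c_v is each voxel's calibrated concentration and the capture region is
the contour dilated by the system FWHM to recover blur spill-out.

**ICG reference test.** Mono-exponential clearance C(t) = C₀e^(−kt) fitted
log-linearly on samples at 0, 5, 10, 15, 20 min; R15 = 100·e^(−15k),
PDR = 100·k %/min; normal means R15 < 10.0 and PDR > 18.0 (strict).

**Statistics.** Pearson r with Fisher-z CIs; ROC by the rank formulation
with Youden-optimal cutoffs (midpoint candidates, ties to higher
sensitivity); Kaplan-Meier/log-rank and Breslow-ties Cox regression via the
survival package; composite 12-month transplant-free survival recoding
(transplant and loss to follow-up count as events) on by default.

## Worked example

Simulate a 1200 mL liver carrying 30% of a 166.5 MBq dose, scan it with
8 mm system blur and Poisson noise, then quantify:

```r
library(qspect)
grid  <- grid_spec(c(128, 128, 128), 3.3)
model <- calibration_model(6807.3, 39.0)
dose  <- dose_record(166.5, injection_to_scan_min = 30)

a_scan <- convert_activity(decay_correct(dose), "MBq", "uCi")
liver  <- sphere_spec(1200, grid_extent_mm(grid) / 2, 0.30 * a_scan / 1200)
scan   <- add_poisson_noise(
            apply_system_blur(rasterize_phantom(liver, grid, model), 8), 42)

seg <- iso_contour_segment(scan, 41)
organ_quant(seg, model, dose, organ = "liver")
#> Liver quantification (threshold 41.0%)
#>   volume 1194 mL, activity 1280 uCi
#>   %QLU = 30.13, %ID/mL = 0.02523 (decay correction on)
```

The 41% contour recovers 1194 of 1200 mL (0.5% volume error) and a %QLU of
30.13 against the constructed truth of 30 — the volume, activity and uptake
chain closing to within noise. The ICG side:

```r
fit_icg_kinetics(c(0, 5, 10, 15, 20), c(7.9, 5.6, 4.1, 3.0, 2.2))
#> ICG kinetics (log_linear): k = 0.063619 /min
#>   R15 = 38.51% (abnormal), PDR = 6.362 %/min (abnormal)
```

A retention of 38.5% at 15 minutes is far above the 10% normal limit — the
pattern of a severely reduced functional reserve.

## Layout

- `R/` — grid/phantom simulation, segmentation, calibration, quantification,
  ICG, statistics, cohort simulator, NIfTI/CSV/JSON I/O, pipeline
- `src/` — Rcpp 6-connected 3-D component labelling
- `vignettes/qspect-methods.Rmd` — models, design decisions, simulator
  scope and limitations
- `tests/testthat/` — unit, property and acceptance suites
- `scripts/acceptance.R` — the reproduction script above
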