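---
title: "Quantitative liver SPECT/CT: models, calibration and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative liver SPECT/CT: models, calibration and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qspect)
```

## The problem

Functional hepatic reserve drives prognosis in decompensated cirrhosis, but
the standard quantitative reference — the indocyanine green (ICG) clearance
test — needs timed blood sampling and is sensitive to hepatic blood flow.
Tc-99m sulfur colloid is phagocytosed by Kupffer cells, so the fraction of an
injected dose that localizes in the liver on SPECT/CT is a direct,
non-invasive proxy for functional liver mass. `qspect` implements the full
quantitative chain for that measurement:

1. **Phantom standardization** — find, per volume range, the fixed
   iso-contour threshold that best recovers known object volumes.
2. **Calibration** — a regression mapping reconstructed counts/cc to
   activity concentration (uCi/cc).
3. **Organ quantification** — liver/spleen volume, percent quantitative
   liver/spleen uptake (%QLU, %QSU) and percent injected dose per mL
   (%ID/mL).
4. **ICG kinetics** — retention at 15 min (R15) and plasma disappearance
   rate (PDR) from a timed dilution series, as the reference comparator.
5. **Prognostic statistics** — Pearson correlation, ROC with Youden-optimal
   cutoffs, Kaplan-Meier/log-rank, and Cox regression.

No patient images or records ship with the package. Two simulators — a
digital phantom generator and a synthetic cirrhosis cohort generator — are
first-class, tested components that stand in for the scanner and the clinic.

## Segmentation and volumetry

An object is segmented by thresholding at a fixed percentage of the
*reference maximum* — the hottest voxel inside the analysis box — and keeping
the largest 6-connected component. Two choices deserve comment:

* **The threshold is relative to the in-box maximum, not the image
  maximum.** Liver and spleen are contoured independently from one scan by
  drawing a box around each; the spleen's threshold must not be diluted by
  the liver's hotter voxels.
* **Volume is the raw voxel count times the voxel volume.** No sub-voxel
  interpolation: the estimator is exactly reproducible by brute-force
  enumeration, and the threshold sweep absorbs systematic bias.

Standardization sweeps thresholds 19–52% in 1-point steps against phantoms
of known volume. Per range, the selected threshold minimizes the *summed*
absolute volume error across the range's phantoms (ties go to the lower
threshold), and the quality of the standardization is summarized by the
Pearson correlation between estimated and true volumes at that threshold.
The three default ranges are 6–30 mL, 500–1500 mL and 2400–3200 mL.

A real protocol drew regions on coronal slices; here contouring is fully
3-D, which subsumes slice-wise drawing for connected objects and is the
documented deviation.

## Calibration and units

The calibration model is a straight line, `counts/cc = slope × uCi/cc +
intercept`, fitted by ordinary least squares from phantoms of known
concentration. Internal canonical units are uCi/mL for concentration, mL for
volume, MBq for administered dose (converted with the exact bridge
1 uCi = 37 kBq) and counts for voxel values. Inverting the line can produce
negative concentrations where counts fall under the background intercept;
these clamp to zero and the clamp count is reported, never silently
discarded.

The phantom simulator applies the same line *forward*, including the
intercept, so simulated reconstructions carry the nonzero background plateau
that real attenuation-corrected images show. The reference coefficients used
in examples and simulation defaults are slope 6807.3 and intercept 39.0.

## Organ quantification

For a segmentation with mask volume $V$ and an injected activity $A_0$
decay-corrected to scan time ($A = A_0 \cdot 2^{-t/T_{1/2}}$, Tc-99m
half-life 360.4 min; correction on by default and recorded in the output),

$$\%\mathrm{QLU} = 100 \cdot \frac{\sum_{v \in \text{capture}} c_v \,
\mathrm{vox}_{cc}}{A}, \qquad
\%\mathrm{ID/mL} = \frac{\%\mathrm{QLU}}{V},$$

where $c_v$ is the calibrated concentration of voxel $v$. The identity
`%ID/mL × volume = %uptake` holds to float precision by construction.

**The capture region.** System blur pushes part of a convex organ's counts
just outside its iso-contour: for a sphere of radius $r$ and blur s.d.
$\sigma$, the boundary layer lost by summing only inside the
volume-matching contour is approximately $1.2\,\sigma/r$ of the total — a
6% underestimate for a 1200 mL organ at 8 mm FWHM, which would defeat the
5% end-to-end accuracy the method targets. The activity integral therefore
runs over the contour dilated by the blur FWHM (the *capture margin*,
recorded in the segmentation; zero for unblurred data), while the volume
estimate stays tied to the undilated contour. The margin assumes the
background around the organ is cold; with a warm background it would
over-collect, which is the main caveat of the default.

## ICG kinetics

A standard dilution curve (absorbance at 805 nm vs known concentration,
Beer–Lambert linearity) converts measured absorbances into blood
concentrations. Clearance is mono-exponential, $C(t) = C_0 e^{-kt}$, fitted
by default with log-linear OLS over the full sampling grid (0, 5, 10, 15,
20 min); the bedside two-point ratio $R15 = 100\,C(15)/C(0)$ is available
as an alternative. Then $R15 = 100\,e^{-15k}$ and $\mathrm{PDR} = 100\,k$
in %/min. The $t=0$ sample is included by default (a mixing-phase exclusion
flag exists, default off).

Reference limits: retention is normal when R15 < 10.0% and clearance normal
when PDR > 18.0 — boundary values are abnormal. The clinical reference for
PDR is often quoted in mL/min; observed cohort PDR values of ~5–7 are only
consistent with %/min, so the package computes PDR in %/min and applies the
18.0 limit numerically to that scale. The discrepancy is inherited from the
source protocol and is flagged here rather than resolved.

## The statistics layer

* `pearson()` — r, t-transform p (n−2 df), Fisher-z 95% CI.
* `roc_with_youden()` — AUC by the rank (pairwise-concordance) formulation
  with half credit for ties, which equals the trapezoidal area under the
  empirical curve. Direction is auto-detected (severity markers *fall* with
  disease; ICG retention *rises*) and recorded. Cutoff candidates are
  midpoints between adjacent distinct scores plus two sentinels; ties in J
  break toward higher sensitivity, then the lower cutoff.
* `km_logrank()` / `cox_regression()` — product-limit curves, log-rank
  chi-square, and partial-likelihood Cox fits with Breslow tie handling,
  via the survival package; monotone-likelihood fits are rejected with the
  offending covariate named.
* Outcome recoding: for 12-month *transplant-free* survival, transplant and
  loss to follow-up count as events. That composite rule is unusual enough
  to be explicit: `recode_outcomes(cohort, recode = TRUE)` is the default
  analysis path, and standard death-only censoring is one flag away.

## The cohort simulator

One latent severity factor $s \sim N(0,1)$ drives every marker:
$x = \mu + \sigma(\lambda s + \sqrt{1-\lambda^2}\,\varepsilon)$, so the
correlation between two markers is the product of their loadings. CTP
scores discretize to 5–15 (classes A 5–6, B 7–9, C 10–15) and MELD to 6–40;
%QLU, %QSU and R15 clamp to their physical ranges with clamp counts logged.
PDR is derived from R15 through the mono-exponential relation rather than
drawn independently, keeping the pair internally consistent.

Default means/SDs and loadings were solved once, at design time, against
the published structure of a 109-patient decompensated-cirrhosis cohort:
the %QLU–MELD correlation (−0.743), the %QLU–ICG-R15 correlation (−0.72),
CTP class proportions near 10/56/43, a class-C conditional mean %QLU of
15.9, and an arm split of 68:41. A single factor cannot reproduce an
arbitrary correlation matrix — matching the %QLU–MELD block and the
class-conditional means forces the %QLU–CTP correlation to about −0.82
(stronger than the published −0.728); the defaults deliberately prioritize
the MELD block and the conditional means, and that trade-off is the main
structural limitation to keep in mind when reading simulation results.

Survival is exponential with log-hazard linear in $s$ (log-HR 0.8 per SD)
and treatment arm, censored administratively at 12 months. Baseline rates
are *solved* — by integrating the severity frailty out — so the marginal
12-month survivals hit the configured targets (51% control, 75% treated)
exactly in expectation; the implied treatment hazard multiplier is recorded
as an attribute. Follow-up values shift by arm (+5.1 %QLU under treatment,
−1.1 under control, SD 8), matching the reported paired changes.

What the simulators do *not* emulate: projection-space physics (attenuation,
scatter, detector response — blur plus Poisson noise stand in for all of
it), organ shapes (spheres and cylinders only), intra-organ uptake
heterogeneity, longitudinal marker trajectories beyond two visits, and any
mechanism linking G-CSF to CD34 counts beyond two configured means. Passing
tests therefore demonstrate the *estimators* are correct and calibrated
under the stated noise model, not that the clinical effect sizes would
reproduce in new patients.

## Numerical choices

* Blur: separable Gaussian, $\sigma = \mathrm{FWHM}/2.3548$ per axis,
  reflection padding, kernel truncated at $4\sigma$ and renormalized — total
  counts are conserved to float precision, not just 0.1%.
* Default grid 128³ at 3.3 mm isotropic (a 128×128 clinical matrix at zoom
  1.5); default system FWHM 8 mm, a plausible post-reconstruction
  resolution for a Butterworth-filtered SPECT/CT. Neither value is a
  published instrument constant; both are configurable everywhere.
  8 mm (rather than ~10 mm) keeps 6 mL spheres — diameter 22.5 mm, barely
  seven voxels — recoverable to 5% at a common range threshold, which is
  the accuracy envelope the standardization procedure targets.
* Voxel membership is by voxel-centre inclusion; partial-volume effects are
  supplied by the blur, not by fractional weighting.
* Threshold-sweep ties break toward the lower threshold; range membership
  uses a 1e-9 relative tolerance (analytic sphere volumes reproduce their
  nominal values only to float error).
* Degenerate inputs error early and specifically: all-zero volumes ("no
  signal"), single-concentration calibration designs, constant covariates,
  single-class ROC labels, missing severity strata.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make Monte-Carlo assertions sharp but cheap: 128³ phantom
grids for standardization and end-to-end quantification; 1000-replicate ICG
noise studies; 200 replicates of n = 1000 for Cox hazard-ratio recovery and
coverage; n = 10,000 cohorts for correlation and Kaplan-Meier targets; a
64³ grid for the byte-identity pipeline checks.

## Known limitations

* The capture margin assumes a cold background; quantifying organs embedded
  in warm background needs a background-subtraction step that is out of
  scope here.
* Thresholds standardized on spheres transfer to organ-shaped objects only
  approximately; the per-range correlation is the honest summary of that
  transfer, and real protocols re-standardize per scanner.
* The single-factor cohort model understates the independence of spleen
  metrics from liver severity at small n (its loadings are small but not
  zero).
* The Cox layer handles neither time-varying covariates nor competing
  risks; the composite-event recoding is a pragmatic, documented choice,
  not a competing-risks analysis.
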