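Package: qspect
Title: Quantitative Liver SPECT/CT Volumetry, Calibration and Hepatic
    Function Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Phantom-based standardization and quantification of
    Tc-99m sulfur colloid liver/spleen SPECT/CT. Provides digital
    phantom simulation (rasterization, system blur, Poisson noise),
    fixed-threshold iso-contour segmentation with threshold-sweep
    standardization, counts-to-concentration calibration regression,
    per-organ uptake metrics (volume, percent quantitative liver and
    spleen uptake, percent injected dose per millilitre), indocyanine
    green retention and plasma disappearance rate kinetics, a
    prognostic statistics layer (Pearson correlation, ROC with Youden
    cutoffs, Kaplan-Meier/log-rank, Cox regression, group
    comparisons), and a synthetic decompensated-cirrhosis cohort
    generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
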