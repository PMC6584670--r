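Package: radtraj
Title: Longitudinal Radiomic Trajectory Biomarkers for Survival Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delta-radiomics survival analysis of serial CT lesion
    measurements. Extracts first-order and morphological features (volume,
    surface area, density, skewness and kurtosis of positive attenuation
    values, histogram entropy, core-region entropy) from 3D regions of
    interest, aggregates multiple target lesions by volume weighting, and
    condenses each feature's longitudinal trajectory into three summary
    statistics: the trapezoidal area under the trajectory (AUC1), the
    least-squares slope over time (beta), and a signed trapezoidal area in
    which decreasing segments subtract (AUC2). Volume trajectories are
    classified into six response/progression patterns. Prognostic modelling
    dichotomizes markers at the most significant log-rank cutpoint, screens
    candidates by univariate Cox regression and variance inflation, selects a
    multivariate Cox model by bidirectional stepwise AIC, and evaluates the
    resulting linear risk score with censoring-weighted time-dependent ROC
    curves. A synthetic cohort generator with known trajectory patterns and
    proportional-hazards outcomes supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
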