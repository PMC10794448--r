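Package: plaquetrend
Title: Geometric IVUS Morphometry and Prediction of Coronary Plaque
    Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end framework for studying coronary atherosclerotic
    plaque progression and regression from paired baseline/follow-up
    intravascular ultrasound (IVUS) pullbacks. Frame-wise lumen and vessel
    contours are converted into geometric descriptors (areas, plaque
    burden, eccentricity, circularity, curvature irregularity and
    roughness, plaque-distribution angles), resampled into uniform
    longitudinal signals, co-registered across time points, partitioned
    into regions of interest under several criteria, and condensed into
    region-wise features (order statistics, Shannon entropy, first Fourier
    harmonic). A gradient-boosted regression-tree model of the change in
    percent atheroma volume is trained and evaluated under repeated
    stratified group-aware cross-validation, with mutual-information
    feature selection, exact TreeSHAP attribution, and post-hoc
    per-region/per-pullback classification indices. A seeded synthetic
    cohort generator with plantable progression structure makes every
    stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
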