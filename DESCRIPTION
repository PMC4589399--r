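Package: dynFDG
Title: Compartmental Kinetic Analysis of Dynamic FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of dynamic FDG-PET studies in
    small animals: a two-tissue (three-compartment) FDG kinetic model with an
    exact analytic solution, Levenberg-Marquardt estimation of the rate
    constants K1, k2, k3, k4 and the fractional blood volume VB, the net
    influx constant Ki = K1*k3/(k2+k3), Patlak graphical analysis, an
    image-derived input function with plasma-to-whole-blood calibration,
    intensity-band region-growing refinement of manually drawn ellipsoid
    ROIs, static SUV/SUVmax analysis, nonparametric group comparison
    (Kruskal-Wallis with exact-permutation option and Dunn post-hoc tests),
    and a synthetic-data generator (subject time-activity curves and 4D
    phantoms) for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
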