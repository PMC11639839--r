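Package: remeval
Title: Random Encounter Model Density Estimation and Its Sensitivity to
    Camera Placement and Day-Range Misspecification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating animal density from camera-trap data with
    the random encounter model (REM) and for evaluating how the estimator
    responds to violated sampling requirements.  Includes exact simulation of
    continuous-time movement processes (Brownian motion, Ornstein-Uhlenbeck,
    integrated OU, and OU-foraging), corridor-biased movement, sector-viewshed
    camera simulation, day-range estimation by exact Gaussian likelihood with
    AICc model selection, independent-detection filtering, camera-level
    bootstrap confidence intervals, placement-by-velocity scenario analysis
    with percent relative difference, and Poisson/negative-binomial trend
    models for literature study counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
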