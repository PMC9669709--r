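Package: faceutility
Title: Latent Utility Estimation over a Morphometric Face Space via
    Gaussian Process Ordinal Regression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating latent psychological utility functions
    (e.g., perceived cuteness) over a low-dimensional morphometric face
    space from ordinal (Likert) ratings.  Builds the face space from 2-D
    landmark configurations by generalized Procrustes analysis,
    symmetrization and principal component analysis, and renders shapes at
    arbitrary principal-component coordinates via thin-plate spline warps.
    Fits Gaussian process ordinal regression with Laplace inference and
    evidence-based hyperparameter selection, drives upper-confidence-bound
    sequential experimental designs, benchmarks predictions against
    proportional-odds ordinal logistic regression by leave-one-out
    cross-validation, and pools per-rater utility surfaces into an averaged
    utility with Gaussian-mixture moments and extremum localisation.  A
    synthetic-data module simulates landmark populations with planted
    principal-component structure and ordinal raters that respond through a
    thresholded noisy latent utility, enabling end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
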