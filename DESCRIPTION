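Package: phaseaudit
Title: Design Diagnostics and Internal Validation for Logistic Regression
    Models of Locust Phase State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing binary logistic regression models of
    two-phase (solitarious/gregarious) phenotype data. Provides an
    iteratively reweighted least squares fitting engine that tracks
    coefficient trajectories, detects complete and quasi-separation
    (including an exact separating-hyperplane feasibility check on small
    problems), screens predictors for collinearity and sign redundancy,
    audits events-per-variable sample-size adequacy, and internally
    validates fitted models by bootstrap optimism correction of Somers'
    Dxy rank discrimination and the logistic calibration line.
    Coefficient-of-variation inference (Feltz-Miller asymptotic test)
    contrasts scale-free dispersion comparison with scale-dependent
    Bartlett tests, and morphometric-ratio "normalization" of behavioral
    traits is implemented together with the analyses that expose its
    pitfalls. Synthetic-data generators emulate a latent-axis two-trait
    simulation and locust-like phase populations in which behavioral and
    morphological traits respond to crowding on decoupled timescales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
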