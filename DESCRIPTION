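Package: triflow
Title: Triple Decomposition of Velocity Gradients for Intraventricular
    Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse gridded blood-flow velocity fields by the
    triple decomposition of the velocity gradient tensor into irrotational
    strain, rigid-body rotation and pure shear, computed through a
    standardized real Schur factorization.  Includes the von Mises-like
    scalar shear stress used in shear-induced platelet-activation models,
    volume-averaged modality time series and thresholded 3D structure
    extraction, a parameterized planar two-half-ellipse mitral-valve
    orifice model with an edge-to-edge (clip) repair variant, cardiac
    phase detection from left-ventricular volume curves, deterministic
    synthetic fixtures with closed-form gradients, VTK image-data and CSV
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
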