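Package: mosfetcf
Title: LET-Dependence Correction Factors for MOSFET In Vivo Proton Dosimetry
Version: 0.1.0
Authors@R: person("mosfetcf", "developers", role = c("aut", "cre"),
    email = "mosfetcf@example.org")
Description: Tools for correcting the linear-energy-transfer (LET) dependence
    of MOSFET detectors used for in vivo dosimetry in therapeutic proton
    beams.  Provides a simplified Monte Carlo (SMC) proton transport engine
    on voxelized relative-stopping-power phantoms, a pencil-beam algorithm
    (PBA), analytic pristine Bragg and spread-out Bragg peak (SOBP) curve
    models, a residual-range indexed MOSFET response model, and the
    correction-factor machinery (SMC-, PBA- and depth-based) that converts
    raw MOSFET readings into dose, together with synthetic beam, curve and
    head-like phantom fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
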