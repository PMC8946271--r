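Package: tbtplan
Title: Treatment Plan Optimization for Simultaneous Interstitial
    Hyperthermia and High-Dose-Rate Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based planning framework for ThermoBrachyTherapy, the
    simultaneous delivery of high-dose-rate brachytherapy and capacitively
    coupled radiofrequency interstitial hyperthermia through dual-function
    applicators.  Provides a synthetic pelvic phantom generator, an
    electroquasistatic finite-difference field solver, a steady-state Pennes
    bioheat solver with per-electrode temperature superposition, a TG-43
    point-source dose engine, the temperature-dependent linear-quadratic
    (TDLQ) model for equivalent physical dose, dose-volume and 3D gamma-index
    metrics, and a particle-swarm optimizer for electrode amplitudes under
    radiotherapeutic dose-volume constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
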