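Package: minflow
Title: Min Protein Pattern Formation Under Advective Bulk Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates self-organized MinD/MinE surface patterns on a
    membrane coupled to an advected bulk solution and quantifies how bulk
    flow steers their propagation.  Implements the mass-conserving
    reaction-diffusion-advection dynamics of the MinE-switch kinetics (full
    switch model plus skeleton and reduced-switch variants) on a laterally
    periodic domain with the bulk dimension integrated out, linear
    stability analysis with dispersion relations and flow-driven
    instability thresholds, adiabatic sweeps over flow velocity and the
    MinE:MinD density ratio including hysteresis and multistability, and
    wave-crest velocimetry of fluorescence time-lapse stacks with a
    ground-truth synthetic stack generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
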