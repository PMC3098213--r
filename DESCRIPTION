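Package: aucBD
Title: Brownian Dynamics Simulation of Analytical Ultracentrifugation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts time-dependent concentration profiles c(r,t) in the
    sector-shaped cell of an analytical ultracentrifuge by Brownian dynamics
    of independent sedimenting particles. Supports sedimentation-velocity and
    sedimentation-equilibrium experiments, with reproducible per-particle
    random streams, radial-dilution-aware binning of particle counts into
    normalized concentration profiles, a conservative finite-volume solver of
    the Lamm equation used as a deterministic cross-check, and molar-mass
    recovery from equilibrium profiles by the classical linearized
    exponential fit. Ships presets for four reference solutes spanning a wide
    range of sedimentation-to-diffusion ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), parallel, optparse, jsonlite, knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
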