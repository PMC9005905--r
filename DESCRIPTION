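Package: pulsetree
Title: One-Dimensional Arterial Pulse Wave Simulation and Pulse Wave
    Velocity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pressure and flow wave propagation in a branching
    network of compliant arteries by integrating the one-dimensional
    blood-flow equations with three-element Windkessel outflow boundaries
    and a time-varying elastance left-ventricle inflow model. Provides
    tools for arterial-tree topology surgery (staged removal of the renal
    arteries and transplantation of a renal branch onto the external
    iliac artery), for perturbing arterial wall distensibility uniformly,
    by diameter class, or from in-vivo override tables, and for measuring
    carotid-femoral, carotid-radial and radial-digital pulse wave
    velocity from simulated waveforms with the foot-to-foot
    maximum-second-derivative method at 900 Hz. Includes a reduced
    reference arterial tree calibrated to standard haemodynamic operating
    conditions and synthetic-waveform generators for validating the
    transit-time estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
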