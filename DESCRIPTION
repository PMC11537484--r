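Package: photoclamp
Title: Phototransduction Cascade Models, Exact Inversion, and
    Light-Adaptation Clamp Stimulus Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward biochemical models of rod and cone phototransduction
    (opsin and phosphodiesterase activation, cGMP hydrolysis and synthesis,
    calcium feedback onto guanylate cyclase) with built-in consensus
    parameter sets for primate and mouse rods and cones; exact inversion of
    the cascade from photocurrent back to light stimulus; and design of
    "light-adaptation clamp" stimuli that force the nonlinear cascade to
    produce chosen target responses (symmetric sinusoidal responses,
    negation of step-induced gain changes, scaled response kinetics).
    Includes small-signal linear-filter fitting, Nelder-Mead parameter
    estimation with shared-parameter consensus fits, MSE-doubling
    sensitivity ranges, sloppy-model Hessian analysis, response metrics,
    photon-flux calibration, and generators for the stimulus protocols used
    to constrain the models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
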