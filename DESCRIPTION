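Package: mesodiff
Title: Molecular Transport in Lamellar Lipid Mesophases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulation and closed-form theory for the
    diffusion of guest molecules (drugs, amino acids) in lamellar lipid
    mesophases. Implements piecewise-parabolic toy models and tabulated
    potentials of mean force U(z) with a position-dependent diffusion
    coefficient D(z), an overdamped Ito integrator with the spurious-drift
    correction, mean-square-displacement estimators for the parallel and
    perpendicular diffusion coefficients, and analytic relations linking the
    partition coefficient (logP) to the lateral and effective macroscopic
    diffusion coefficients, including an exact periodic-medium closed form
    used as an independent check of the stochastic estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
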