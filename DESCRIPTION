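Package: dpdiss
Title: Dissipative Particle Dynamics of Dissolving Surfactant Lamellar Phases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A coarse-grained dissipative particle dynamics (DPD) engine and
    analysis stack for studying the dissolution of surfactant lamellar phases
    in water, with or without oil additives. Provides bead-spring force-field
    containers for amphiphile chains, an NVT integrator with the standard
    momentum-conserving DPD thermostat, builders for the two-stage dissolution
    experiment (equilibrate a concentrated lamellar box, crop, stitch to water
    behind repulsive walls, relax), concentration-profile and homogeneity
    analysis, micelle detection by chain clustering with aggregation-number
    statistics, and a five-zone compartment model of dissolution kinetics with
    least-squares inference of the phase-transformation and diffusion
    constants. Synthetic-data generators (planted micelles, ideal fluids,
    step concentration fields, zonal curves) make every analysis stage
    testable without long simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
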