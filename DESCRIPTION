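Package: phenoswitch
Title: Multistability, Probability Landscapes, and Phenotype Switching in a
    Two-Gene Cancer Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of a dimensionless
    two-gene regulatory circuit (a zeb1-like self-activator repressing a
    cdh1-like self-activator) whose attractors are identified with the
    stem-like (S), basal (B), and luminal (L) phenotypic states of breast
    cancer cells.  Provides fixed-point enumeration and stability
    classification, one- and two-parameter bifurcation scans, a critical
    Hill-coefficient search, Euler-Maruyama simulation of the Langevin
    dynamics with basin-occupancy and first-passage estimators, stationary
    solutions of the two-dimensional Fokker-Planck equation and the
    Waddington-style effective potential -ln P, and one-dimensional
    mean first-passage-time theory (exact double-integral and
    steepest-descent forms) including barrier heights and the noise
    threshold at which the preferred switching direction reverses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
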