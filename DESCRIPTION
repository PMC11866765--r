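Package: mahi
Title: Multipole-Accelerated Hamiltonian Interpolation for Constant-pH
    Lambda Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Periodic-boundary Coulomb electrostatics via a fast multipole
    method (FMM) with a renormalized lattice operator and tinfoil/vacuum
    boundary handling, an Ewald-summation oracle, and an engine for
    lambda-dynamics of titratable sites. Exact Hamiltonian-interpolation (HI)
    forces on lambda pseudoparticles are recovered from a single charge-scaled
    electrostatics pass by per-site-form corrections (box-box, lattice, dipole
    compensation); a charge-interpolation (QI) mode, the analytic harmonic
    HI-QI potential difference, a Langevin lambda-dynamics integrator with
    transition counting and transition-state-theory barrier analysis, random
    benchmark-system generators, and accuracy-scan drivers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
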