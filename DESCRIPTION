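Package: spatialresist
Title: Multi-Compartment Branching-Process Models of Drug-Resistance
    Evolution Under Spatially Heterogeneous Drug Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Continuous-time multi-type branching-process models for the
    de novo evolution of drug resistance when drug concentrations differ
    across spatial compartments (drug sanctuaries, metastatic lesions,
    concentric shells of a solid tumor around a blood vessel).  Birth
    rates follow a Hill dose-response fitness landscape; cells divide,
    die, mutate stepwise toward resistance, and migrate between
    compartments.  The package integrates the backward probability
    generating function (PGF) equations of the process to compute
    treatment escape probabilities, conditional relapse curves and mean
    times to resistance for arbitrary initial cell censuses, recovers
    joint resistant-cell-count distributions by discrete-Fourier
    inversion of the PGF on the unit torus, compares the competing
    migration-mutation and mutation-migration pathways to resistance
    (including the analytic low-rate dominance condition), and ships an
    exact Gillespie stochastic simulator of the same process as an
    independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
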