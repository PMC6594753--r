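Package: cftrpot
Title: Kinetic and Thermodynamic Analysis of CFTR Potentiator Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how lipophilic potentiator drugs such as
    ivacaftor (Vx-770) act on CFTR chloride channels in excised membrane
    patches. Implements four compartmental drug-partition/binding schemes
    (one or two intramembrane binding sites crossed with one or two membrane
    compartments), integrates them over arbitrary drug-application protocols,
    and fits them globally to ensembles of normalized macroscopic current
    time courses under an octanol/water partition constraint. Also provides
    steady-state dose-response theory and modified Hill fitting, empirical
    activation/deactivation kinetics, single-channel idealization and
    closed-open-blocked (C-O-B) dwell-time analysis with a dead-time
    correction, spectrophotometric solubility/partition arithmetic, van't
    Hoff solution thermodynamics, and seeded synthetic-data generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
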