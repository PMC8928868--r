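Package: phenocycle
Title: Seasonal Obligate-Killer Parasite-Host Dynamics and Virulence Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a semi-discrete model of a monocyclic, obligate-killer
    parasite infecting a seasonally emerging host. Within-season transmission
    follows a system of delay differential equations solved semi-analytically;
    between-season host reproduction follows a Beverton-Holt map. Tools are
    provided to iterate the seasonal map, classify attractors (parasite-free,
    endemic equilibrium, quasiperiodic cycling), scan bifurcations over the
    virulence trait, map phase boundaries across phenological patterns, compute
    mutant invasion fitness and evolutionarily stable virulence, and run
    stochastic adaptive-walk simulations of virulence evolution under full
    demographic feedback or a constant-cohort control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
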