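Package: fugapop
Title: Population-Based Simultaneous Fugacity Modelling of PCB Fate in
    Aquatic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multimedia fugacity model for the fate and bioaccumulation of
    polychlorinated biphenyls (PCBs) in lakes. Air, water and sediment
    compartments are coupled to per-species biotic compartments through
    explicit D-value transport coefficients (diffusion, deposition, gill
    exchange, dietary uptake with a trophic-magnification-factor gut-feces
    partition, egestion, mortality), with temperature-dependent fugacity
    capacities and their analytic time derivatives, allometric population
    dynamics with an energy-mass primary-producer closure, and both
    steady-state (linear solve) and dynamic (stiff ODE) solutions of the
    coupled fugacity equations. A deterministic toy-lake scenario generator,
    a flux ledger with mass-balance auditing, tidy result tables and ggplot2
    visualisations are included.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
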