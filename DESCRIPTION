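Package: paracortex
Title: Agent-Based Simulation of T Cell Motility, Chemotaxis, and
    Trafficking in the Lymph Node Paracortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An on-lattice stochastic agent-based simulator of T cell
    behaviour in the lymph node paracortex. T cells perform a persistent
    random walk on a dense three-dimensional lattice ("blob") in which the
    number of available sites always matches the number of cells, with a
    one-step double-occupancy rule that lets cells pass each other. Cells
    enter at random sites within an inner sphere, leave probabilistically
    from the Moore neighbourhoods of discrete exit portals, and may be
    biased toward portals by a probabilistic chemotaxis scheme that mixes
    a chemotaxis-only jump distribution into the motility kernel. The
    number of exit portals is maintained by an empirically calibrated
    power law of the population so that steady-state trafficking
    reproduces a configured residence time, and an inflammation-driven
    growth-factor/vascularity ODE sub-model modulates the influx rate to
    reproduce lymph node expansion and contraction during an immune
    response. Includes calibration tools, transit-time statistics,
    chemotaxis-index estimators, and tidy accessors and plots for all
    result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
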