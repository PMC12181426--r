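Package: rnaisim
Title: Deterministic and Stochastic Simulation of RNA Silencing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a four-compartment model of
    RNA interference kinetics (dsRNA, RISC, RISC-mRNA complex, mRNA) and its
    stochastic extension with multiplicative white noise on four rate
    constants. Provides the deterministic vector field, steady states with
    feasibility analysis, the next-generation-matrix basic reproduction
    number, linear-growth and Lipschitz diagnostic constants, Euler-Maruyama
    and Milstein integrators (both a literature-literal and a standard Ito
    variant), seeded trajectory and ensemble simulation with moment
    statistics, empirical strong-convergence-order estimation, exponential
    p-stability condition checking with Lyapunov diagnostics, figure-regime
    scenario presets, CSV/JSON trajectory serialization, and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
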