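Package: sarcosim
Title: Stochastic-Mechanical Half-Sarcomere Simulation with
    Metabolite-Dependent Cross-Bridge Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a one-dimensional, two-filament half-sarcomere as a
    network of Hookean springs driven by a three-state actomyosin cross-bridge
    cycle whose rate constants depend independently on ATP concentration and on
    the ADP-phosphate product. Provides the lattice geometry and parameter set,
    a direct linear solver for the mechanical equilibrium after every chemical
    transition, a fixed-step kinetic Monte Carlo simulator with a compiled core,
    the closed-form one-myosin steady state used as an analytic surrogate, and
    sweep utilities that map duty ratio, force, and ATP consumption over
    metabolite concentration grids, including fitting of the effective sliding
    distance that best reconciles simulation with the analytic solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
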