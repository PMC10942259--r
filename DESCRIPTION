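Package: metatip
Title: Tipping Points from Weak Mutualism in Stochastic Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and mean-field analysis of generalized Lotka-Volterra
    metacommunities with demographic noise and global dispersal. Weakly
    mutualistic interactions between species, combined with stochastic local
    extinctions and recolonization through dispersal, generate a
    metacommunity-wide strong Allee effect: a critical dispersal rate below
    which the extinct state is stable, a tipping point, bistability and
    hysteresis, none of which exist in the deterministic well-mixed dynamics.
    The package provides a seeded Poisson-update simulator (compiled core),
    the self-consistent stationary abundance distribution of the matching
    one-population Fokker-Planck problem, bifurcation scans with critical and
    tipping-point dispersal rates, random symmetric interaction communities
    with survivor statistics, density-dependent dispersal, and reproducible
    experiment drivers for bistability, hysteresis and species-removal
    protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
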