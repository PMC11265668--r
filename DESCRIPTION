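Package: chromspread
Title: Particle-Based Reaction-Diffusion Simulation of Histone
    Modification Spreading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of histone-modification spreading from a
    nucleation site, in which enzyme, RNA and enzyme-RNA-complex particles
    diffuse in a two-dimensional disc (Brownian dynamics with reflecting
    boundaries) and react with a one-dimensional nucleosome lattice or with a
    frozen two-dimensional polymer configuration of the chromatin fibre.
    Includes a reaction-only Gillespie comparator (contact-process kinetics
    with an optional space-dependent spreading rate), exact small-lattice
    master-equation oracles, self-avoiding-walk and random-walk polymer
    generators, and the statistics layer (profile width, kurtosis, radial
    shell densities, complex-proximity profiles) used to distinguish
    reaction-diffusion from purely kinetic spreading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
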