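Package: protocell2d
Title: Two-Trait Protocell Evolution with Mutation Kernels and Tau-Leaping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of a population of pre-biological
    protocells over a two-dimensional trait space of enantiomeric excess and
    inherited information. A truncated-Gaussian mutation kernel combined with
    trait-dependent replication and decay rates drives either deterministic
    (forward-Euler integrodifferential) or stochastic (fixed-step tau-leaping
    in integer molecule counts with an exact matter-conservation invariant)
    dynamics in a closed food/waste-recycling reaction scheme. Also provides
    the stationary Fredholm eigenproblem for the steady trait distribution,
    the convection-diffusion approximation of the dynamics with full and
    small-mutation closed-form coefficient fields, summary statistics,
    evolution-stage segmentation, and species (connected-component) detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    generics,
    jsonlite,
    yaml,
    rlang,
    ggplot2,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
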