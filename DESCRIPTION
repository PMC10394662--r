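Package: ppdkinetics
Title: Kinetic Modelling of the Enantioselective Hydrogenation of
    1-Phenyl-1,2-Propanedione
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a simplified first-order irreversible kinetic model of
    the cinchonidine-modified Ir/TiO2-catalysed hydrogenation of
    1-phenyl-1,2-propanedione: a nine-species, twelve-reaction network, exact
    matrix-exponential forward solution with Bateman closed-form cross-checks,
    bound-constrained least-squares estimation of the rate constants with 95%
    marginal highest-probability-density intervals (Laplace or MCMC),
    parameter correlation diagnostics, synthetic concentration-time data
    generation, pathway classification into preferential, intermediate and
    negligible routes, and a small command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
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
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
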