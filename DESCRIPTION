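Package: epnet
Title: Sparse Bayesian Inference of Causal Molecular Networks by Expectation Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sparse causal molecular networks (gene regulatory or
    signalling) from time-series or steady-state perturbation data. The
    dynamics of each molecule are described by a sigmoidal ordinary
    differential equation with explicit soft-intervention (perturbation)
    nodes; an Euler discretization turns the system into a dynamic Bayesian
    network with tied weights, and per-node spike-and-slab regression is
    solved by Expectation Propagation, yielding posterior edge weights and
    inclusion probabilities. Includes B-spline interpolation and smoothing
    preprocessing, a synthetic benchmark generator with known gold-standard
    networks, threshold-free AUROC/AUPR evaluation, DREAM4-style file
    readers and writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
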