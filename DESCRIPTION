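Package: hgtcoex
Title: Coexistence of Competing Microbes Under Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for generalized Lotka-Volterra
    competition between microbial species that exchange mobile genetic
    elements by horizontal gene transfer. Implements the classic and
    HGT-extended competition models, closed-form two-species coexistence
    theory, Monte-Carlo coexistence-feasibility ensembles, diversity-limit
    detection, growth-rate-variability experiments, and piecewise-
    deterministic growth-rate perturbation protocols, with Shannon-Hill
    diversity as the outcome measure. Results are tidy tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
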