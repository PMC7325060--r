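Package: osteosim
Title: Stochastic Hexagonal-Lattice Simulation of Bone Metastasis Growth and
    Radium-223 Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based Monte-Carlo simulator of osteolytic prostate-cancer
    bone metastases on a regular hexagonal lattice. Tumour cells divide,
    die or stay quiescent on a 24-hour internal clock; under Radium-223 the
    event probabilities depend on the distance of each cell from the bone
    interface (logistic dose-response) and on the decaying activity of the
    radioisotope (exponential, 11-day half-life). Includes calibration
    fitters for the logistic and decay models, ensemble statistics
    (coefficient of variation, replicate-count selection), one-at-a-time
    sensitivity analysis, NRMSE validation, regimen comparison and
    distance-dependence studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
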