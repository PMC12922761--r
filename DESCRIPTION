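Package: tmlemiss
Title: Targeted Learning of Average Potential Outcomes with Incomplete
    Exposures and Confounders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Doubly and multiply robust estimation of average potential
    outcomes E(Y^a) when both the exposure and a subset of the confounders
    are partially missing. Implements identification under missing-at-random
    and two outcome-independent missing-not-at-random assumption sets,
    targeted maximum likelihood estimators (TMLE-A and TMLE-B) with
    influence-function-based inference, iterated-conditional-expectation and
    inverse-probability-weighted plug-ins, complete-case and
    multiple-imputation pathways, exact identification oracles on enumerable
    discrete laws, and a Monte-Carlo study harness with synthetic-data
    generators for three missingness scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
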