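Package: cesim
Title: Microsimulation of Cesarean Section Rates and Access to Obstetric Surgical Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A first-order Monte Carlo state-transition microsimulation of
    women's reproductive lifetimes under alternative policies for access to
    comprehensive emergency obstetric care (CEmOC) and cesarean section (CS)
    rates in India. Women cycle annually through non-pregnant, pregnant,
    post-hysterectomy and dead states; each pregnancy resolves through a
    delivery-episode decision tree (with or without facility access) that
    generates obstetric events, costs in 2016 USD and quality-adjusted life
    years. The package provides a validated parameter registry with
    probabilistic-sensitivity distributions, an exact expected-value evaluator
    used as a verification oracle, grid calibration of non-indicated CS
    probabilities to target CS rates, cost-effectiveness frontier and ICER
    construction, outcome reporting per 10,000 women with national
    extrapolation, and one-way, two-way and probabilistic sensitivity analyses.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
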