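Package: fenocea
Title: Cost-Utility Analysis of FeNO-Guided Paediatric Asthma Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state weekly Markov cohort model for the cost-utility of
    asthma management guided by fractional exhaled nitric oxide (FeNO)
    monitoring in children, compared with standard symptom-guided therapy.
    Provides moment-matched parameter distributions (beta, gamma, lognormal,
    Dirichlet) for probabilistic sensitivity analysis, DerSimonian-Laird
    random-effects pooling of trial relative risks, deterministic base-case
    and one-way (tornado) sensitivity analyses, second-order Monte Carlo
    simulation with cost-effectiveness plane, acceptability curve and
    expected value of perfect information statistics, and a synthetic trial
    generator for end-to-end testing. Results are returned as tibbles and
    plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
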