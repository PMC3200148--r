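Package: prevalloc
Title: Resource Allocation Across Preventive Health Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Priority setting across portfolios of preventive health
    interventions by constrained QALY maximization. Provides a linear
    programming allocator over intervention-by-age-group cells with budget,
    demand and professional-capacity constraints, efficiency-frontier tracing
    with segment incremental cost-effectiveness ratios and constraint shadow
    prices, league tables of average cost-effectiveness ratios, a simplified
    multi-state Markov cohort simulator producing lifetime-discounted QALY and
    cost differences versus usual care, a seeded generator of realistic
    allocation problems, and sensitivity analyses over capacity limits,
    discount rates and time horizons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
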