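Package: strokecea
Title: Markov Cohort Cost-Utility Analysis of Post-Stroke Functional Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm, six-state, time-inhomogeneous Markov cohort model of
    post-stroke functional recovery on the modified Rankin Scale (mRS), with
    trial-style panel data simulation, per-interval transition probability
    estimation with hazard-based re-timing onto a 3-month cycle, discounted
    cost and QALY valuation, ICER and dominance analysis, one-way
    deterministic sensitivity analysis (tornado), probabilistic sensitivity
    analysis by Monte Carlo simulation, and cost-effectiveness acceptability
    curves. Tidyverse-native: functions take data frames and return tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
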