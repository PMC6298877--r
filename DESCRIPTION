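Package: brjoint
Title: Benefit-Risk Joint Models for Longitudinal Drug Response and
    Time to Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Shared-random-effects joint models linking a longitudinal
    biomarker response (change from baseline in HbA1c) to the time to a
    first drug side effect, with current-value and cumulative-value
    association structures, alongside the two standard comparators: a
    last-observation-carried-forward time-dependent Cox model and a
    6-month landmark Cox model with delayed entry. Includes a synthetic
    trial-cohort generator emulating a 5-year head-to-head diabetes drug
    trial (bimonthly visits in year 1, quarterly thereafter), cohort
    preparation implementing the response definition, eligibility and
    censoring rules, and tidy reporting of hazard ratios per 1% greater
    absolute HbA1c response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
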