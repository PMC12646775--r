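Package: egotriad
Title: First- and Second-Order Structure of Egocentric Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing social contact diaries that record both the
    number of daily contacts (first-order network structure) and the
    connectedness of pairs of reported contacts (second-order structure, or
    local clustering). Implements hierarchical overdispersed-Poisson
    regression for daily contact counts, and hierarchical logistic
    regression for contact-triangle connectedness with a group-aware
    "any-of-m" likelihood that accounts for contact events reported as
    groups. Includes a synthetic survey generator with known ground truth,
    certainty-cutoff sensitivity rules, trimming of extreme group
    observations, MCMC diagnostics (rank-normalised split R-hat, bulk and
    tail effective sample size) and WAIC model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
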