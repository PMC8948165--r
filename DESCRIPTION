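Package: ltfhpp
Title: Liability Phenotypes from Family History and Age of Onset for GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates posterior mean genetic liabilities under an
    age-dependent liability threshold model, conditioning on case-control
    status, age or age of onset, sex, and birth-year-specific cumulative
    incidence for genotyped individuals and their family members (the
    LT-FH++ phenotype).  Also provides the comparison phenotypes
    (case-control status, GWAX proxy cases, LT-FH), Aalen-Johansen
    cumulative incidence estimation under competing risks, a liability-scale
    simulation framework with case ascertainment, and association-testing
    and power-comparison utilities.  The truncated multivariate normal
    Gibbs sampler at the core is implemented in C++ via Rcpp.
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
    survival,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mvtnorm,
    testthat (>= 3.0.0),
    truncnorm,
    withr
Config/testthat/edition: 3
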