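Package: earlychange
Title: Latent Classes of Early Symptom Change in Web-Based Depression
    Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies and uses patterns of early change in repeated
    depression-symptom measurements (PHQ-9) from a 12-week web-based
    intervention. Fits piecewise growth mixture models with fixed
    factor loadings by EM under a full-information likelihood,
    enumerates latent classes with a two-fold BIC and bootstrapped
    likelihood ratio test rule, classifies pre-post reliable change
    (Jacobson-Truax), and links class membership to outcome and
    adherence through contingency analysis with Pearson residuals,
    one-way ANOVAs with Bonferroni post hocs, hierarchical regression,
    and multinomial logistic prediction. Includes a synthetic-data
    generator that emulates the study design with ground-truth labels,
    and an end-to-end pipeline producing tidy report tables.
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
    nnet,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
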