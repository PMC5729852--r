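Package: acemirt
Title: Twin ACE Variance Moderation with Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian estimation of the classical twin ACE variance
    decomposition with measured-moderator interaction (ACE x M) and a Rasch
    item response measurement model. Variance components are moderated on the
    log scale, which keeps the model uniquely identified, in contrast to
    path-moderation parametrizations whose squared paths admit multiple
    equally likely solutions. Includes a twin-family item-response simulator,
    a sum-score comparison analysis that reproduces the spurious
    interaction effects induced by floor and ceiling effects, highest
    posterior density intervals, replication-level power and bias summaries,
    and Joanes-Gill skewness estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    withr,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
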