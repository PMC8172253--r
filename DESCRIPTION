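Package: lvcomposite
Title: Latent Variable Analysis of Composite Responder Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint latent-variable (conditional grouped continuous) modelling of
    composite responder endpoints that mix two continuous, one five-level ordinal
    and one binary component, as used in systemic lupus erythematosus trials.
    Provides maximum-likelihood fitting of the latent Gaussian model, marginal
    (covariate-standardised) response probabilities and odds-ratio inference with
    delta-method standard errors, the standard-binary and augmented-binary
    comparator analyses, a clinical-trial simulator with normal and skew-normal
    error distributions for assessing bias, coverage, power and relative
    precision, and a bootstrap bias-correction procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    numDeriv,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
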