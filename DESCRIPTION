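Package: grfa
Title: Generalized Residual Fit Assessment for Linear Normal Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of linear normal common factor
    models together with a generalized-residual framework for goodness-of-fit
    assessment beyond mean and covariance structures. Summary quantities
    defined on a grid of latent-variable values are compared between their
    sample averages and model-implied expectations; Monte-Carlo moment
    estimation and an expected-information correction yield the asymptotic
    covariance of the (optionally transformed) residuals, from which pointwise
    z-tests and an overall chi-square test based on a truncated
    eigendecomposition weight matrix are constructed. Turnkey tests for
    latent-density normality, manifest-variable linearity, and
    manifest-variable homoscedasticity are included, along with synthetic-data
    generators and a replication harness for Type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
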