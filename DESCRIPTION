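Package: boostsel
Title: Stability Selection with Error Control for Component-Wise
    Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variable selection with finite-sample error control for
    high-dimensional regression. Combines component-wise functional
    gradient descent boosting (linear, P-spline and ridge/categorical
    base-learners for Gaussian and binomial losses) with stability
    selection on half-size subsamples, including complementary pairs
    subsampling and the worst-case, unimodal and r-concave upper bounds
    on the per-family error rate. Ships generators for two simulation
    scenarios (linear logistic and Gaussian additive models with
    independent or Toeplitz designs), a log-linear phenotype-microarray
    interaction pipeline with a synthetic fixture generator, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
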