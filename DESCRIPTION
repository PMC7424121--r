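Package: morphcp
Title: Categorical Perception Analysis for Morphed-Face Identity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-alternative forced-choice experiments on
    morph continua between face identities. Turns trial-level response tables
    into percent-response psychometric curves with label-flip symmetrization
    for arbitrary-label control continua, participant-level bootstrap
    confidence intervals, per-morph-level effect sizes and the asymmetry-bias
    statistic, and mixed-model inference: a binomial generalized linear mixed
    model with logit link fitted by the Laplace approximation (penalized
    iteratively reweighted least squares inner step), a Gaussian linear mixed
    model for log reaction times, Type-3 Wald chi-square tests, and estimation
    of the point of subjective equality (categorical boundary) per condition.
    Includes a synthetic-data generator that emulates the two experimental
    designs: lapse-adjusted logistic choice with condition-specific boundary
    shifts, crossed participant and continuum random intercepts, and
    ambiguity-dependent lognormal reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    car,
    ggplot2,
    optparse
Config/testthat/edition: 3
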