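Package: weightmsm
Title: Survey-Weighted Multistate Models for Childhood Weight Status Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating continuous-time Markov multistate models of
    childhood weight status (underweight, healthy weight, overweight, obesity)
    from interval-censored panel surveys with complex sampling designs. Includes
    LMS growth-reference z-scoring and centile classification, survey-weighted
    maximum-likelihood estimation of transition intensities with piecewise
    age-band heterogeneity and covariate hazard ratios, delete-one-cluster (JKn)
    jackknife replicate-weight variance estimation, Markov cohort traces for
    validation and projection, and a synthetic cohort generator with known
    ground truth for method checking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    parallel
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
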