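Package: alexnn
Title: Questionnaire Predictors of Alexithymia via Regression, Mediation,
    Deep Networks and Hidden-Layer Subgroup Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for survey studies of
    alexithymia and its questionnaire predictors. Scores six self-report
    instruments (TAS-20, DASS-21, AAQ-II, SACS, MAIA-2, PANAS-SF), runs
    distributional and collinearity diagnostics, fits AIC-guided backward
    stepwise regressions and noncentral-F power analytics, estimates simple
    mediation models with percentile-bootstrap confidence intervals for the
    indirect effect, trains deep tanh backpropagation networks with momentum
    and weight decay, clusters upper-hidden-layer activations with a
    two-stage Ward then K-means procedure to discover participant subgroups,
    and profiles each subgroup with Cohen's d effect sizes (odds-ratio
    conversion for binary variables). A synthetic-data generator with
    planted linear, mediated and nonlinear-subgroup effects makes every
    stage testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml,
    jsonlite,
    withr,
    lmtest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
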