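Package: hte3
Title: Design of Three-Level Randomized Trials for Treatment Effect
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic design machinery for three-level randomized trials
    (participants nested in subclusters nested in clusters): nested
    exchangeable intraclass correlation structures and their eigenvalue
    algebra, closed-form variances and design effects for tests of
    treatment-by-covariate interaction (heterogeneous treatment effects)
    and the covariate-adjusted average treatment effect under cluster-,
    subcluster-, or participant-level randomization, power and sample-size
    solvers (normal, between-within t, and noncentral chi-square
    references), a generative simulator for linear mixed analysis of
    covariance trial data, and a fast restricted maximum likelihood
    inference engine for balanced three-level designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
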