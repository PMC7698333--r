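Package: nploa
Title: Nonparametric Limits of Agreement for Method Comparison Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of Bland-Altman limits of agreement (LoA) when the
    paired differences cannot be assumed normal.  Provides six nonparametric
    quantile estimators for the 2.5% and 97.5% tail quantiles -- a two-order-
    statistic sample quantile (SQ), the Harrell-Davis estimator (HD), a
    Bernstein-polynomial estimator (BP), the Harrell-Davis estimator on a
    level-crossing empirical distribution (HDlc), the first Sfakianakis-
    Verginis estimator (SV), and the Navruz-Ozdemir estimator (NO) -- together
    with the classical parametric LoA, percentile-bootstrap confidence
    intervals for the limits, and a Monte-Carlo engine that evaluates the
    coverage probability and root-mean-squared error of each estimator across
    a panel of six reference distributions.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
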