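Package: nof1seq
Title: Serial Correlation and Sequential Designs for Personalized (N-of-1) Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for personalized (N-of-1) crossover
    trials. Quantifies how AR(1) serial correlation and washout periods inflate
    false-positive rates of intervention-effect tests, provides
    serial-correlation-aware tests (AR(1) generalized least squares estimated
    by profile maximum likelihood, and Newey-West heteroskedasticity- and
    autocorrelation-robust standard errors), a truncated Wald sequential
    probability ratio test for response rates aggregated over personalized
    trials, and a bootstrap-calibrated sequential probability ratio test for
    the quickest detection of a regression slope in single-subject monitoring
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    zoo,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lmtest,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
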