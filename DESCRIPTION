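Package: oddpred
Title: Conditional Oddball Design, Temporal EFA of ERPs and Bayesian
    Behavioural Modelling
Version: 0.1.0
Authors@R:
    person("Oddpred", "Developers", email = "oddpred@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how rarely encountered conditional rules
    shape auditory prediction. Generates constrained oddball stimulus
    sequences in which two deviant types carry opposed conditional
    repetition rules (0.8 versus 0.2 repetition probability), simulates
    multi-channel event-related-potential (ERP) epochs with a known
    low-rank temporal factor structure as well as single-trial detection
    behaviour, and analyses both: epoch-level preprocessing and condition
    averaging, temporal exploratory factor analysis (Empirical Kaiser
    Criterion, covariance-based extraction, Promax rotation, regression
    factor scores, microvolt-scale reconstruction), signal-detection
    summaries with the log-linear correction, JZS default Bayes factors
    with fixed-n design analysis, and a hierarchical lognormal power-law
    response-time learning model fitted by adaptive MCMC with WAIC and
    PSIS-LOO model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
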