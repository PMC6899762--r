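Package: wedesign
Title: Information-Theoretic Phase I/II Dose-Finding with a Continuous
    Efficacy Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a seamless Phase I/II dose-finding design for
    trials with a binary toxicity endpoint and a continuous efficacy
    endpoint (the "WE" design). A continuous outcome is mapped to the
    unit interval through a logistic (or probit / complementary log-log)
    transformation and combined with the toxicity probability in an
    information-theoretic trade-off criterion that scores each regimen's
    distance from a target toxicity-efficacy profile. Per-regimen Beta
    and Normal-inverse-Gamma conjugate posteriors drive plug-in
    estimation, adaptive top-two randomised allocation under coherence,
    and time-varying safety and futility constraints. The package ships
    a full trial simulator with correlated toxicity-efficacy outcome
    generation, delayed and missing efficacy observation models,
    operating-characteristic aggregation over replicated trials, and
    grid-search calibration of prior means.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
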