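Package: sstmediate
Title: Stop-Signal Race-Model Metrics, Insulin Resistance, and Bootstrap Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulate and score stop-signal task (SST) sessions under the
    independent horse-race model: median go response time (mGRT), the
    critical stop-signal delay (cSSD) at which half of go responses can be
    countermanded, and the stop-signal response time (SSRT = mGRT - cSSD),
    with the standard performance-based inclusion filters and race-model
    consistency checks.  Computes HOMA-IR from fasting glucose and insulin,
    runs covariate-adjusted regression screens linking metabolic measures,
    region-of-interest activation contrasts, and task performance, and
    quantifies simple mediation (X -> M -> Y) with percentile-bootstrap
    confidence intervals, the kappa-squared effect size, and a combined
    evidence rule.  Includes a synthetic cohort generator with a
    configurable insulin-resistance to striatal-activation to go-speed
    mediation structure and a sequential pipeline producing machine-readable
    run reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
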