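Package: vppg
Title: Quantitative Venous Photoplethysmography for the Candlestick-Prayer Maneuver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of venous photoplethysmography
    (VPPG) recordings obtained during the Candlestick-Prayer (Ca-Pra)
    positional maneuver used in the work-up of suspected thoracic outlet
    syndrome. Provides a single-compartment hemodynamic simulator of forearm
    venous volume with controllable outflow and inflow impairment (including
    synthetic patient cohorts), extraction of the PPGmax, End-Ca-PPG and
    %PPGmax emptying statistics, rule-based classification of the qualitative
    trace morphologies, empirical ROC analysis with Hanley-McNeil and DeLong
    standard errors and the closest-to-corner optimal cutoff, diagnostic
    confusion-table metrics, and exact integer reconstruction of 2x2 tables
    from published rounded sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
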