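Package: thrombodyn
Title: Thrombin Dynamics Analysis of Thrombin Generation Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes measured thrombin generation (TG) curves into their
    underlying pro- and anticoagulant processes: prothrombin conversion and
    thrombin inactivation by antithrombin and alpha-2-macroglobulin. A kinetic
    model of thrombin inactivation (pseudo-first-order decay set by plasma
    antithrombin, alpha-2-macroglobulin and fibrinogen levels) is combined with
    the measured free-thrombin time course to reconstruct the prothrombin
    conversion curve and its summary parameters (PCtot, PCmax, T-AT, T-a2M,
    TDC), alongside the standard descriptive TG parameters (lag time, peak,
    time-to-peak, ETP, velocity index). Includes cohort-level reference-range
    estimation and non-parametric group comparisons, a forward simulator and
    synthetic-cohort generator for validation, and a batch analysis pipeline
    with delimited-text input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
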