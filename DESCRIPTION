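Package: scedmed
Title: Mediation Analysis for Single-Case Experimental Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests hypothesized mediators of intervention outcomes in
    single-case experimental designs (SCEDs). Quantifies the treatment-to-
    mediator and treatment-to-outcome paths with Tau-U nonoverlap statistics
    and piecewise (segmented) phase regression, proxies the mediator-to-
    outcome path with cross-lagged correlations whose significance is
    assessed against Monte-Carlo AR(1) surrogate series, and combines the
    evidence under a joint-significance decision rule with temporal-
    precedence and specificity checks. Includes a synthetic-data generator
    with known ground truth for operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
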