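Package: ccdlnm
Title: Case-Crossover Distributed Lag Nonlinear Models for Daily
    Temperature and Self-Harm Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying short-term associations between ambient
    temperature and daily counts of intentional self-harm and suicide
    death using a time-stratified case-crossover design. Implements
    natural cubic spline cross-bases for distributed lag nonlinear
    models, conditional quasi-Poisson regression with stratum effects
    absorbed by profile likelihood, QAIC-guided knot selection, and
    cumulative and lag-specific relative-risk curves with delta-method
    confidence intervals, maximum-risk-temperature location, and
    percentile-contrast relative risks. A synthetic-data module
    generates weather series, holiday calendars, and individual-level
    case records from a known exposure-lag-response surface so the
    whole pipeline is testable without restricted registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
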