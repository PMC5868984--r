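Package: spcurve
Title: Semiparametric Mixed Models for Longitudinal Medical-Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Penalized-spline (truncated power basis) mean curves inside a
    linear mixed model with subject random intercepts and optional serial
    correlation (exponential or Gaussian), for densely sampled longitudinal
    monitoring data such as 24-hour ambulatory blood pressure recordings.
    Provides a stepwise class of group-comparison model structures, plug-in
    first-derivative ("rate of change") curves, pointwise and simulation-based
    simultaneous confidence bands for between-group difference curves,
    trace-based effective numbers of parameters with adjusted AIC model
    selection, likelihood-ratio and approximate F tests, and a synthetic
    ambulatory-blood-pressure generator with known truth for simulation and
    coverage studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
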