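Package: seedaging
Title: Seed Viability Decay Modelling and Longevity Estimation from
    Accelerated Aging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits candidate viability-decay curves (three- and two-parameter
    Weibull, logistic, Gompertz) to replicate-level accelerated-aging assay
    data by bounded multistart nonlinear least squares, extracts the median
    viability time L50 with bootstrap intervals, ranks models by residual
    sum of squares based AIC/BIC, regresses L50 on chronological seed age
    (quadratic or four-parameter Weibull-form) and extrapolates the
    longevity upper bound by root finding. Includes germination-trial
    summaries with Tukey HSD letters, tetrazolium stained-area
    quantification on seed cross-section images, and seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
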