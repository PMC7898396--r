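Package: lrfgpp
Title: Gross Primary Production from an Asymptotic Light Response Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models daily ecosystem gross primary production (GPP) with a
    Mitscherlich (asymptotic) light response function whose two parameters,
    photosynthetic capacity (F_opt) and quantum efficiency (alpha), are
    coupled to NDVI through biome-specific logistic curves. Provides the
    full calibration chain against daily flux-tower style records
    (quality filtering, semi-monthly parameter extraction, binned
    percentile regression, logistic/Gaussian environmental constraint
    fitting, percentile sensitivity search, bootstrap parameterization),
    NDVI spike filtering and double-logistic upper-envelope smoothing,
    gridded upscaling to daily GPP fields with area-weighted global
    budgets, trends and detrended inter-annual variability, model
    evaluation with spatial, inter-annual and intra-annual decomposition,
    and a synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    rpart,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
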