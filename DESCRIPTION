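Package: spawnsite
Title: Spawning-Site Fidelity from Passive Acoustic Telemetry and
    Standardized Haul-Seine Catch Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyze reproductive site fidelity of estuarine
    fish at an inlet spawning site. Processes passive acoustic telemetry
    detections into weighted-means positions, detection zones, residence
    metrics (days detected, total period, residence index) and a binomial
    additive mixed model of daily spawning-site presence with cyclic
    day-of-year and lunar-phase smooths, a sex effect and per-fish random
    intercepts. Standardizes zero-inflated haul-seine catch rates with
    kernel-density region classification, a two-part binomial/lognormal
    hurdle model selected by forward AIC, and Monte-Carlo combination of
    the sub-models into annual index distributions. Includes synthetic
    data generators for both data streams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    mgcv,
    MASS,
    emmeans,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
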