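Package: nichecast
Title: Ensemble Species Distribution Modelling and Climate-Scenario
    Habitat Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for projecting marine species habitat suitability under
    climate change with an ensemble of presence/pseudo-absence niche models.
    Covers occurrence record cleaning and gridding, hierarchical bathymetry and
    distance-to-coast filtering, environmental-space thinning, pseudo-absence
    generation outside a percentile-trimmed convex hull, eight candidate
    algorithms including a non-parametric Mahalanobis-rank niche model (NPPEN),
    Continuous Boyce Index cross-validation and ensemble selection, per-cell
    delta bias correction of general circulation model fields, multi-scenario
    projection of an Environmental Suitability Index with range-change and
    Exclusive Economic Zone summaries, and a synthetic-world generator with
    known niche truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    mgcv,
    nnet,
    randomForest,
    xgboost,
    pracma,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
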