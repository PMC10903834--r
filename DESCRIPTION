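Package: climvuln
Title: Ensemble Species Distribution Modelling and Climate-Change
    Vulnerability Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess the vulnerability of species assemblages to
    climate change from presence-only occurrence data and gridded climate
    layers.  Implements occurrence cleaning with step-by-step provenance,
    collinearity-based climate variable selection, per-species ensembles of
    three presence-background modelling techniques weighted by the true
    skill statistic, dispersal-limited projection onto future climate
    scenarios, IUCN criterion A3 threat classification from projected range
    change, pixel/family/ecoregion vulnerability summaries, and a resampled
    all-subsets beta-regression analysis of the climatic drivers of relative
    vulnerability.  A virtual-species simulator with known climatic niches
    and true range changes makes the full pipeline testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    glmmTMB,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml
Config/testthat/edition: 3
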