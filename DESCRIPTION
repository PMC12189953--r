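Package: mareniche
Title: Ensemble Niche Modeling and Conservation-Gap Analysis for Marine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for climate-driven marine
    species distribution analysis: occurrence quality control (duplicate,
    suspicious-coordinate and land filtering, 5.5 km spatial thinning),
    correlation-filtered permutation-importance variable selection, ensemble
    presence/pseudoabsence niche modeling with TSS-optimized binarization,
    projection onto warming scenarios with per-pixel range-change accounting,
    multi-species hotspot delineation, and overlay against marine protected
    areas, exclusive economic zones and vessel-traffic density. A synthetic-world
    generator with known Gaussian niches provides ground truth so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    glmnet,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
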