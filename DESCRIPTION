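Package: fluorisk
Title: Deterministic and Probabilistic Health Risk Assessment for Fluoride
    in Drinking Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing non-carcinogenic health risk from fluoride
    in drinking water across age cohorts. Implements the USEPA chronic
    daily intake and hazard quotient (HQ) exposure algebra, district-level
    summaries, fluorosis endpoint prevalence classification, Monte Carlo
    uncertainty propagation with contribution-to-variance sensitivity
    analysis, a feed-forward neural-network surrogate that predicts HQ
    from exposure features, and a constrained synthetic-data generator
    that reproduces published per-site summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
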