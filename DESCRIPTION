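Package: socbuffer
Title: Social Buffering of Maternal Loss in Gorilla Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of the demographic and social consequences
    of maternal loss in group-living primates, built around long-term
    mountain gorilla monitoring designs. Constructs Simple Ratio Index
    association networks from focal-scan data for paired six-month windows
    around a maternal-loss incident, tests orphans' change in network
    position against node-label permutation nulls, models dyadic
    relationship change with spline-smoothed mixed models, and quantifies
    survival and dispersal effects with time-varying Cox proportional
    hazards, a Bayesian Siler mortality trajectory analysis compared by DIC,
    and binomial/Gaussian generalized linear models. Includes a seeded
    synthetic-data generator that emulates the focal sampling design so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    survival,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
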