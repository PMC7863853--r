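Package: worrytype
Title: Functional and Dysfunctional Worry Typologies from Two-Wave Survey Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies survey respondents' worry about catching COVID-19 into
    unworried, functional, and dysfunctional groups from worry, precaution,
    feeling-safer, and quality-of-life items, following the functional-fear
    tradition in fear-of-crime research. Provides the unit-record data model
    and codebook validation for two-wave panels, derived indices (COVID
    adversity count, summative emotion score with Cronbach's alpha,
    re-engagement change score, risk-perception recodes), quota weights on
    gender and age (cell and raking modes), wave-to-wave group transition
    matrices, and association models (multinomial logit, negative binomial,
    Poisson, linear) with principal-component covariate scores. A seeded
    synthetic panel generator reproduces the statistical structure the
    analyses assume, so the full pipeline is testable without access to the
    original survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
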