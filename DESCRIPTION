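Package: halfsibNe
Title: Effective Mother Size from Within-Cohort Maternal Half-Sibling Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of contemporary effective mother size (Ne) from the
    number of maternal half-sibling pairs observed among offspring sampled
    from a single cohort. Implements a reproduction model with negative
    binomial (overdispersed) offspring numbers and among-mother variation in
    reproductive potential, a Chapman-type nearly unbiased estimator of Ne
    with closed-form bias and variance formulas, an age-structured fecundity
    model based on von Bertalanffy growth, an individual-based pedigree
    simulator for validating the estimators, and a Wright-Fisher
    temporal-method comparator (Nei-Tajima F statistic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
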