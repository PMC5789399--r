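Package: phylloseal
Title: Quantitative Analysis of Humidity-Dependent Wound Self-Sealing in
    Succulent Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the self-sealing movement of wounded
    succulent leaves and the mechanics behind it.  Converts tracked
    three-point time series into relative bending angles, analyses tensile
    force-displacement records (stress, strain, tensile strength, elastic
    modulus, Poisson's ratio), evaluates a turgor-based tissue-stiffness
    model for parenchymatous tissues, and provides the rank-based
    repeated-measures inference used for humidity x time sealing
    experiments (two-way within-subject ANOVA on rank-transformed data
    with Mauchly's sphericity test, Greenhouse-Geisser correction and
    Bonferroni-adjusted pairwise t-tests).  A synthetic-experiment
    generator with known ground truth makes every stage testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
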