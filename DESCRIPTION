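Package: plastevo
Title: Plastic and Genetic Phenotype Changes Across Environmental Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the two phases of adaptation to a new
    environment: the immediate plastic response and the subsequent genetic
    response. Implements constraint-based metabolic modelling (flux balance
    analysis, minimization of metabolic adjustment, and a biomass-constrained
    MOMA variant) to predict flux states of an organism before a shift,
    right after it, and once re-adapted; classifies any trait measured at
    those three stages into reinforcing, reversing, restored, facilitating
    and related categories; and provides the exact binomial tests, the
    analytic null ratio (1-q)/(1+q), a transcriptome ingestion pipeline for
    experimental-evolution expression matrices, and seeded synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
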