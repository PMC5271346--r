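Package: airwayturnover
Title: Longitudinal Turnover Analysis of the Preterm Airway Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying within-subject bacterial community turnover
    in longitudinal marker-gene (16S rRNA) studies of ventilated preterm
    infants. Implements multi-sample Shannon beta diversity expressed as a
    Hill number (the effective number of communities among a subject's serial
    samples) with a normalization for unequal sample counts, pairwise
    Morisita-Horn similarity within subjects, log-normal generalized
    estimating equations for repeated-measures group comparisons, and a
    beta-binomial join-point generalized linear mixed model of taxon relative
    abundance over postnatal age with data-driven knot selection. A synthetic
    cohort generator reproduces the sampling design of a multi-site tracheal
    aspirate study (serial aspirates in the first three weeks of life,
    outcome groups of graded severity) so that every stage of the pipeline is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    glmmTMB,
    sandwich,
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
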