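Package: phenoscreen
Title: Behavioral Phenoscore Screening for Larval Zebrafish Sedative Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput behavioral phenotypic
    screening in larval zebrafish. Converts video frame stacks or motion-index
    tables into stimulus-aligned behavioral profiles, builds an archetypal
    reference profile by simulated annealing over replicate positive-control
    wells, scores wells by correlation-based phenoscores, derives significance
    cutoffs by null simulation, quantifies plate quality (Z-factor), calls
    hit and toxic compounds, fits four-parameter logistic dose-response
    curves and efficacy windows, and supports hit-compound cheminformatics
    (Tanimoto fingerprint clustering, guilt-by-association target enrichment,
    normalized binding affinities). A seeded synthetic-data generator emulates
    the behavioral and chemical structure of such screens so that every stage
    is testable without raw video data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
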