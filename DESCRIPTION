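Package: gemscreen
Title: Context-Specific Genome-Scale Metabolic Models and In Silico Drug
    Screening for Glioma Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds context-specific genome-scale metabolic models from
    expression data under a defined extracellular medium and uses them to
    predict critical metabolite exchanges, essential genes, repurposable
    single drugs and synergistic drug combinations, and to rank drug
    candidates against curated evidence tables. Includes a bounded-variable
    simplex engine for flux balance and flux variability analysis, a
    FASTCORE-family context extraction step driven by mixture-model
    discretization of RNA-seq expression, Bliss-independence combination
    scoring with a healthy-control safety check, and a synthetic-data
    generator that plants verifiable ground truth (essential genes,
    narrow-bounded exchanges, synergistic target pairs) in toy networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    mclust,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
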