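Package: scDriverLoad
Title: Cancer Cell Identification in Single-Cell RNA-Seq by Driver
    Alteration Load and Inferred Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies putative cancer cells in full-length-transcript
    single-cell RNA-seq data by combining per-cell counts of putative
    oncogenic driver alterations (matched against a local oncogenicity
    catalog) with inferred copy-number-variation summary scores,
    calibrated against a normal-cell baseline distribution. Includes
    residue-to-genome coordinate mapping with coverage-based absence
    calling (present / absent / insufficient-coverage status per cell
    and alteration), a simplified windowed expression-based CNV scorer,
    nonparametric group statistics, and a seeded synthetic-cohort
    generator producing complete pipeline inputs with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    vcfR,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
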