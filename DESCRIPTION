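Package: ASpanel
Title: Alternative Splicing Panel Analysis from Fragment-Length RT-PCR and
    RIP-qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of high-resolution RT-PCR alternative-splicing panels
    read out by capillary electrophoresis. Converts fragment-analysis peak
    areas into per-sample isoform percentages, summarizes biological
    replicates, tests genotype contrasts for changes in isoform ratio and
    total transcript abundance with tiered effect-size and t-test calls,
    performs hypergeometric enrichment of splicing event classes among
    changed events, classifies dosage-series direct targets of an RNA-binding
    protein, and quantifies in vivo binding from RIP-qPCR Ct tables. Includes
    a seeded synthetic-data generator with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Transcriptomics, GeneExpression,
    DifferentialSplicing, qPCR
RoxygenNote: 7.3.3
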