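Package: phytoarray
Title: Strain-Resolved Analysis of Environmental Functional-Gene
    Microarray Metatranscriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing environmental functional-gene microarray
    metatranscriptomes at strain and phylogroup resolution. The package
    covers probe-to-target summarization (median polish) and quantile
    normalization, negative-control based detection calling, strain
    presence and relative transcript abundance, single-gene differential
    expression with a fold-change-threshold moderated test, ensemble
    gene-set testing combined by Wilkinson's method with a
    taxon-abundance artifact filter, weighted co-expression module
    detection via topological overlap, and non-metric multidimensional
    scaling of sample metatranscriptomes. A synthetic-community data
    generator with a ground-truth ledger makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    jsonlite,
    optparse,
    withr
biocViews: Microarray, Preprocessing, DifferentialExpression,
    GeneSetEnrichment, Network, Transcriptomics, Metagenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
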