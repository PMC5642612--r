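Package: immunosig
Title: Immune Gene Signatures and Centroid-Based Molecular Subtyping of
    Tumour Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds immune gene expression signatures from bulk RNA-seq
    cohorts and assigns samples to molecular subtypes. Provides an immune
    gene panel registry (including a packaged 722-gene pan-cancer immune
    panel), one-vs-rest gene ranking by an ensemble of five discriminators
    with top-fraction signature merging, a dual-centroid nearest-centroid
    classifier with a strict unclassified fallback, hierarchical clustering
    utilities, a PANTHER-style binomial over/under-representation test with
    Bonferroni correction, and a synthetic cohort generator emulating a
    four-cluster immune-activation gradient for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    fgsea,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'centroid.R'
    'enrichment.R'
    'hier.R'
    'io.R'
    'panels.R'
    'preprocess.R'
    'rank.R'
    'pipeline.R'
    'synthetic.R'
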