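Package: senastro
Title: Transcriptome Analysis of Oxidative Stress-Induced Astrocyte
    Senescence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested re-implementation of a complete bulk RNA-seq
    analysis of oxidative stress-induced senescence in human astrocytes:
    negative-binomial differential expression with a conditional exact
    test (median-of-ratios size factors, method-of-moments dispersions
    with a parametric 1/mu fit), gene-ontology and tissue-expression
    enrichment with Fisher's exact test, Benjamini-Yekutieli false
    discovery control, enrichment-ratio/count/FDR filtering, collapsing
    of terms sharing many differentially expressed genes, inverse-
    membership gene weighting, gene-set overlap statistics
    (representation factor and hypergeometric significance), and
    delta-delta-Ct qRT-PCR relative quantification with RNA-seq
    concordance. A seedable synthetic-data generator emulates the
    two-condition, two-replicate study design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
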