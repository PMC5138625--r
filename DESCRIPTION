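Package: lincnet
Title: Long Intergenic Noncoding RNA Identification and Stage-Specific
    Co-Expression Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly analysis of transcriptome catalogs aimed at long
    intergenic noncoding RNAs (lincRNAs): novelty classification of assembled
    transcripts against a reference annotation, a five-stage lincRNA filter
    funnel with an internally trained coding-potential model (ORF, Fickett
    TESTCODE, hexamer usage bias, logistic combination), Jensen-Shannon
    tissue-specificity scores, neighbour-gene cis-correlation with a seeded
    random null, TSS-distance profiles, a from-scratch signed weighted
    co-expression network (soft thresholding, topological overlap, dendrogram
    module detection, module eigengenes, module merging, stage association,
    kME hub extraction), Fisher-exact term enrichment, and a synthetic-data
    generator that plants ground truth for every stage so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Network
RoxygenNote: 7.3.3
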