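Package: lncPloidy
Title: Identification and Allopolyploid Expression Profiling of Long Non-Coding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for identifying long non-coding
    RNAs (lncRNAs) from assembled transcript models and profiling their expression
    across an allopolyploidization series (two diploid parents, their F1 hybrid and
    a derived allotetraploid). Covers class-code comparison of assembled transcripts
    against a reference annotation, coding-potential scoring (longest ORF, Fickett
    TESTCODE, hexamer usage bias, logistic consensus), positional classification,
    transposable-element overlap, subgenome assignment and homoeologous collinearity,
    TPM normalization, mid-parent values, negative-binomial differential expression
    with additivity calls, short time-series model-profile clustering, cis-target
    prediction and hypergeometric GO enrichment. Includes a synthetic-data generator
    with full ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Annotation, DifferentialExpression
RoxygenNote: 7.3.3
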