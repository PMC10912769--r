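Package: gcstab
Title: GC-Content-Dependent mRNA Stabilization Analysis for Ribo-Seq, RNA-Seq and SLAM-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how coding-sequence GC content shapes
    post-transcriptional regulation after depletion of an RNA helicase. Implements
    negative-binomial GLM likelihood-ratio testing of translation efficiency from
    paired Ribo-seq/RNA-seq count matrices, per-gene sequence and expression feature
    extraction from GTF/FASTA annotation, cross-validated random-forest and lasso
    feature-importance ranking, a 5'-coverage-shift statistic that quantifies
    5'-to-3' decay from per-transcript coverage tracks, SLAM-seq T>C conversion
    counting with a labeling-by-depletion stability test, and binned summaries of
    the Ribo-seq/RNA-seq fold-change plane. A synthetic-data generator plants
    GC-dependent regulation in toy transcriptomes, count matrices, coverage tracks
    and conversion tables so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
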