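Package: petalClock
Title: Developmental and Diurnal Petal Transcriptome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq of flower petals sampled
    across developmental stages (bud, one day post-anthesis) and times of
    day (morning, evening). Implements negative-binomial Wald contrasts
    with median-of-ratios normalization and explicit DEG thresholds,
    stage/time gene-set classification with the associated percentage
    arithmetic, a WD40 candidate-gene screen, phylogenetic profiling of a
    query protein by bit-score-ratio conservation scores with clade
    restriction calls, and 2^-ddCt qPCR quantification. A synthetic-data
    module generates count matrices, clade-structured proteomes and Ct
    tables with the statistical structure the analyses assume, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
biocViews: RNASeq, DifferentialExpression, GeneExpression, Transcriptomics,
    Alignment, qPCR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
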