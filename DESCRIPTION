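Package: lncDosage
Title: Genomic Imbalance and lncRNA Regulatory Network Analysis for
    Aneuploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for dosage effects in aneuploid RNA-seq
    experiments, built around the expression-ratio distribution statistic
    used to detect dosage compensation and inverse dosage effects.
    Provides a negative-binomial synthetic-data generator with planted
    dosage-response classes and lncRNA target structure, CPM/FPKM
    normalization and case/control ratio tables, binned ratio-distribution
    and modal-peak analysis, a negative-binomial Wald test for
    differential expression, positional classification of lncRNAs,
    cis (co-location) and trans (co-expression) lncRNA target prediction,
    bipartite lncRNA-mRNA network construction with a full cytoHubba-style
    centrality suite (including maximal clique centrality hub ranking),
    hypergeometric over-representation analysis, and a deterministic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
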