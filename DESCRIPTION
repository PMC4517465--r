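Package: ripTargetome
Title: miRNA Targetome Analysis from Neuron-Specific AGO2 RIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies microRNA target mRNAs from Argonaute-2 (AGO2)
    RNA-immunoprecipitation sequencing of 3'UTR read counts. Implements
    sham-normalized relative enrichment with anchor-window (GAPDH +/- 50
    genes) normalization, minimum-read filtering and four-fold target
    classification; enrichment ranking with cumulative predicted-site
    curves and a Monte-Carlo null; rank-shift detection of transcripts
    released from the RNA-induced silencing complex (RISC) after miRNA
    sponge inhibition; and integration with mRNA-seq fold changes
    (median-of-ratios normalization, Kolmogorov-Smirnov and t tests,
    delta-delta-Ct arithmetic) to quantify target derepression. A
    negative-binomial generative model with planted ground truth emulates
    the RIP/sham/sponge experimental design so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
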