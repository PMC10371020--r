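Package: rdhscape
Title: Genome-Wide RNA:DNA Hybrid Enrichment and Mutagenesis Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping RNA:DNA hybrid (RDH) accumulation and its
    mutagenic consequences on bacterial chromosomes. Implements Bayesian
    inference of strand-specific log2 enrichment of hybrid pull-down over
    input sequencing libraries with a negative-binomial count model,
    spike-in size-factor normalisation, genotype contrasts and qPCR
    delta-delta-Cq quantitation; robust z-scores, rolling medians,
    replication-slope profiling and event-density tracks; feature-level
    aggregation with head-on versus codirectional comparisons (Wilcoxon
    tests, Benjamini-Hochberg FDR, bootstrap confidence intervals) and an
    orientation-by-expression regression; mutation-accumulation-line rate
    estimation with exact Poisson intervals and rate-ratio tests; and a
    Bayesian Poisson regression of per-gene mutation rates with Bayes
    factors against a region of practical equivalence and PSIS-LOO model
    comparison. A synthetic-data generator with planted ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, Bayesian, Coverage, Sequencing, Software
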