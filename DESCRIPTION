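Package: regfine
Title: Integrative Regulatory Fine-Mapping of a GWAS Risk Locus
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting a disease-associated regulatory locus from
    genetic association through chromatin readout to target-gene programs.
    Implements case/control allelic association with fixed-effect
    meta-analysis and Cochran heterogeneity, imputation INFO-score filtering,
    dosage-r2 linkage-disequilibrium block capture and conditional analysis;
    copy-number-restricted Kruskal-Wallis eQTL testing with homozygote fold
    changes; allele-specific ChIP signal analysis with common-variant
    N-masking, exact binomial imbalance tests and input-DNA controls;
    ChIP-qPCR quantitation by standard curve, percent input, fold enrichment
    and allele-preference checks; peak-to-TSS assignment, Hi-C contact
    linking and IUPAC consensus motif scanning; driver-correlated gene
    programs with binomial overlap enrichment and translocation outlier
    Z-scores; and recombination-signal-sequence (RSS) scanning of
    translocation breakpoint flanks. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable end to
    end, and a pipeline driver orchestrates reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
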