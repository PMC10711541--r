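Package: bpscan
Title: Branch Point Sequence Prediction and Variant-Database Constraint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts intronic branch point sequences (BPS) with a position
    weight matrix combined with a distance-weighted octanucleotide background
    model, quantifies nucleotide-resolution evolutionary constraint from a
    catalogue of biallelic SNVs (relative variability of genomic features,
    splice-site and BPS position profiles, Fisher's exact comparison of
    heptamer positions with Bonferroni correction), and audits variant
    databases for exome contamination and erroneous variants using three
    plausibility criteria. A seeded simulator generates genomes (FASTA),
    annotations (GTF) with planted branch points, and variant catalogues
    (VCF) with configurable per-feature constraint, so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
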