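Package: equidiv
Title: Interspecies Nucleotide Divergence and SNP Discovery from Cross-Species Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating nucleotide divergence between a sequenced query
    species and a related reference genome from per-site pileup evidence. Implements
    a binomial maximum-likelihood genotype caller with a platform-aware filter stack
    (depth, RMS mapping quality, homopolymer context), classification of sites into
    fixed interspecies differences versus within-species SNPs, 1-Mb windowed
    divergence and SNP-density statistics with per-chromosome box-plot summaries,
    polymorphism-corrected genome-wide divergence, transition/transversion quality
    control, sequencing-error estimation from hemizygous Y-chromosome sites,
    in-silico reduced-representation-library digestion, and variant-consequence
    annotation against gene models. Ships a two-species genome simulator with a
    complete truth ledger so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
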