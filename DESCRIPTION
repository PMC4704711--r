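Package: mmcsig
Title: Mutational Signature Analysis of Mitomycin C Mutagenesis in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising the genomic footprint of the
    interstrand-crosslinking agent mitomycin C (MMC) in a balancer-based
    Caenorhabditis elegans mutagenesis screen. Provides strain-specific
    variant filtering across a sequenced cohort, six-class substitution
    spectrum tabulation and chi-square comparison, deletion sequence-context
    analysis (5'-CpG-3' dinucleotide enrichment against a genomic background),
    deletion-junction microhomology scoring, balancer-screen genetics
    statistics (forward mutation frequency, three-factor map-distance
    estimation with exact binomial confidence limits), and detection of
    balancer rearrangement boundaries from binned read coverage. A synthetic
    mutagenesis simulator with full ground truth makes every stage testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
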