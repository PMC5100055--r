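Package: crosspurge
Title: Cross-Contamination Purging and Silicon Transporter Classification
    for Multi-Project Transcriptome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and purges cross-contaminant contigs from multi-project
    de novo transcriptome assemblies using percent-identity histogram
    thresholding over masked all-vs-all nucleotide comparisons, with
    RPKM-based arbitration of near-identical contig pairs. Includes a
    symmetric DUST low-complexity soft-masker, a gapless seed-and-extend
    local aligner, a structural classifier for Silicon Transporter (SIT)
    and SIT-like (SIT-L) proteins based on transmembrane-domain counts and
    EGXQ/GRQ motif pairs (with N/C-terminal half splitting), a bootstrap
    support based phylogenetic contamination screen, and a multi-project
    assembly simulator with contamination ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
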