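Package: selax
Title: Selection-Relaxation Screens and Pervasive-Transcription
    Quantification for Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Codon substitution models (GY94-style) with branch-specific
    dN/dS and a selection-intensity parameter k, fitted by maximum
    likelihood on tagged phylogenies; likelihood-ratio tests for
    relaxed versus intensified selection on designated test branches;
    an intersection-based per-gene screen classifying genes as relaxed
    or constrained across branch partitions, with partition-level
    chi-squared and rank statistics; identification and
    radical/conservative classification of lineage-private amino-acid
    substitutions; and quantification of pervasive (intergenic,
    non-repeat-associated) transcription from transcript catalogs and
    per-tissue read counts. Includes seeded synthetic-data generators
    with planted ground truth for every analysis, and readers/writers
    for FASTA, tagged newick, GFF3, BED and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
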