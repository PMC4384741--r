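Package: editcall
Title: Genome-Free Detection of A-to-I RNA Editing from Matched DNA and
    RNA Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects RNA-DNA differences, in particular A-to-I RNA editing
    sites, by comparing matched DNA-seq and RNA-seq reads aligned against a
    de novo transcriptome's open reading frames, without a reference genome.
    Implements two complementary calling procedures ("weak" sites, where the
    edited base is the minority of RNA reads and is tested against the
    sequencing error rate with a binomial model under Benjamini-Hochberg FDR
    control; and "strong" sites, where the RNA-derived consensus carries the
    edited base and every DNA read disagrees with it, scored against a SNP
    prior), together with downstream characterization: mismatch-cluster and
    sequence-context analyses, per-tissue editing-level quantification and
    comparison, codon recoding consequences with context-preserving
    randomization nulls, substitution-score analyses, soft-clip based
    exon-exon junction inference, and a synthetic read simulator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
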