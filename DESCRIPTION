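Package: ereflow
Title: Proteogenomic Analysis of Endogenous Retroelement Expression and the
    MHC-I Immunopeptidome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for joint differential analysis of transcripts
    (genes and endogenous retroelements) and MHC-I-associated peptides:
    empirical-Bayes moderated-t differential expression and abundance with
    Benjamini-Hochberg control, ERE class enrichment against a genomic
    background, peptide physicochemical statistics (GRAVY, aromaticity,
    polar and DNMT2-target residue fractions, C-terminal protease
    association), peptide-to-transcript integration through three-frame
    candidate databases and rphm quantification, and cohort-level
    stratification with ssGSEA, pre-ranked GSEA and median splits. A
    synthetic-data generator with planted, recoverable effect structure
    stands in for RNA-seq and mass-spectrometry inputs so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
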