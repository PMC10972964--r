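Package: vdjkit
Title: Discovery and Annotation of V(D)J Germline Genes and Repertoire Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for motif-based discovery of immune receptor V, D and J germline gene
    segments in genomic DNA. Candidate genes are located by combining conserved amino-acid
    anchors (1st-CYS, CONSERVED-TRP, 2nd-CYS motif, FG), IUPAC nucleotide motifs, splice
    signals and CAC-anchored recombination signal sequences with 12- or 23-nucleotide
    spacers (+/- 1). Candidates are classified as functional, ORF or pseudogene following
    IMGT-style rules, grouped into gene families at a nucleotide identity threshold,
    named by genomic order, and exported as germline libraries with MiXCR-style anchor
    points. The package also computes post-clonotyping repertoire summary statistics
    (V/J usage and pairing, CDR3 spectratype, rank abundance, publicity, convergence,
    amino-acid composition, chimera detection) from AIRR-style clonotype tables, and
    ships seeded simulators for ground-truthed synthetic loci and repertoires.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
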