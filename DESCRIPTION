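Package: srnaloci
Title: Small RNA Locus Discovery, miRNA Annotation and piRNA Cluster Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterisation of small-RNA producing loci from
    short-read data. Provides a synthetic-data generator that plants miRNA
    hairpins and unistrand/dual-strand piRNA clusters with ping-pong and
    phased-biogenesis read structure into toy genomes; read collapsing,
    contaminant subtraction and low-mismatch ungapped genome mapping;
    MirGeneDB-style miRNA locus annotation with seed-based family assignment
    and presence/absence censuses; proTRAC-style piRNA cluster detection with
    1U/10A nucleotide-bias, entropy-logo, ping-pong overlap and phasing
    analytics; and a configuration-driven pipeline with planted-truth
    recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
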