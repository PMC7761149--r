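Package: orthoedit
Title: A-to-I RNA-Editing Discovery with Orthology-Based Conservation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects candidate A-to-I RNA-editing events in highly polymorphic
    genomes from RNA-seq and genomic read alignments: strand-aware pileup-based
    SNV calling restricted to coding regions (A-to-G on forward-strand
    transcripts, T-to-C on reverse), subtraction of genomic SNPs called from DNA
    reads, and per-isoform amino-acid consequence annotation. Candidate events
    are then classified by conservation against a reference species' known
    editing sites via global protein alignment of homologous isoforms and a
    window-of-homology match (window sizes 0, 1, 5 and infinite; conservation
    classes 0-4), and curated for double-stranded RNA context with a
    maximum-base-pairing secondary-structure fold of the pre-mRNA. A seeded
    synthetic-fixture generator with planted truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
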