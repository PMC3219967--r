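Package: ssurecon
Title: Reconstruction of Full-Length SSU rRNA Genes from Short-Read
    Metagenomes by Expectation Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs full-length small-subunit (SSU) rRNA gene
    sequences and their relative abundances from short-read shotgun
    sequencing data.  Reads are iteratively mapped to a candidate
    reference set; an expectation-maximization algorithm assigns
    multi-mapping reads probabilistically, corrects the reference
    consensus sequences base by base from quality-aware read evidence,
    and re-estimates abundances until the sequences stabilize.
    Candidate sequences that converge onto each other are merged and
    candidates showing evidence of multiple strains are split.  Includes
    a deterministic ungapped paired-end read mapper, a SAM/BAM adapter,
    reference-database preparation utilities (length filtering, greedy
    identity clustering, controlled mutation for robustness tests), a
    ground-truthed paired-end read simulator with quality-driven
    substitution errors, and evaluation tools (abundance correlation,
    N50, weighted UniFrac against a supplied tree).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
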