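Package: rflpfinder
Title: Restriction Enzyme Site Search and PCR-RFLP Enzyme Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses REBASE-style restriction enzyme catalogs, locates enzyme
    recognition sites in DNA on both strands using a Boyer-Moore matcher
    generalized to IUPAC-degenerate recognition patterns, and judges which
    enzymes discriminate the alleles of a sequence variation for PCR-RFLP
    genotyping. Accepts plain DNA, IUPAC-coded variation sequences and
    bracketed-allele notation (including indels), supports allele expansion,
    flanking-window extraction, result classification (composite-IUPAC versus
    general recognition sequences, commercial versus non-commercial enzymes),
    batch analysis over many templates, and TSV/JSON/BED reporting. Ships a
    deterministic synthetic catalog generator so all functionality is testable
    without downloading REBASE.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
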