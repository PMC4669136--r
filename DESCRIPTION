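Package: satkit
Title: Characterization of Tandemly Repeated Satellite DNA from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of satellite-DNA repeat families in
    long sequencing reads: k-mer nomination of repeat-rich reads, self-match
    periodicity detection, monomer extraction by wraparound dynamic-programming
    alignment, reference-anchored star multiple alignment and majority consensus,
    internal direct/inverted motif detection, variability and diagnostic-position
    statistics, dimeric higher-order-repeat (HOR) inference from contiguous versus
    non-contiguous monomer similarity, neighbor-joining trees with bootstrap
    support, in-silico restriction-digest ladder prediction, and two-proportion
    tests of repeat abundance between sequencing libraries. Includes a seeded
    generator of tandem-array genomes and pyrosequencing-like read libraries with
    planted ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
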