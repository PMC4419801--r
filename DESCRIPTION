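Package: sweepnet
Title: Selective-Sweep Scans and Interaction-Network Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of recent positive selection in phased
    haplotype panels and relates them to protein-protein interaction
    network centrality. Implements site-frequency-spectrum statistics
    (Tajima's D, Fay and Wu's H, and their joint DH test against an
    empirical genomic background), haplotype-based scans (EHH, iHS) and a
    cross-population composite likelihood ratio scan (XP-CLR), gene-level
    empirical P values combined by Fisher's method, a polarized
    McDonald-Kreitman module with the neutrality index, a sliding-window
    alignment sanitizer with an M7-versus-M8 likelihood-ratio caller, and
    permutation, rank-correlation and trend tests linking selection scores
    to network centrality and gene essentiality. A forward-in-time
    Wright-Fisher simulator with recombination and hard sweeps generates
    panels, backgrounds, scale-free networks, ortholog alignments and
    polymorphism/divergence count tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    seqinr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
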