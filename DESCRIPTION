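Package: mirtarscan
Title: MicroRNA Target Site Scanning, Feature Scoring and Repression Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans 3'-UTR sequences for microRNA seed matches (6mer, 7mer-A1,
    7mer-m8 and 8mer site types) and computes a comprehensive feature set for
    each site and miRNA-mRNA pair: hybridization free energies of the duplex
    and of the seed region (minimum free energy and ensemble variants on a
    built-in nearest-neighbor backend), the site accessibility opening energy,
    the probability of observing at least the seen number of seed matches
    under an order-1 Markov model of the UTR (binomial approximation and an
    exact automaton solution), evolutionary conservation as a branch length
    score and a phyloP-style likelihood-ratio test, and the sequence context
    features AU content, UTR position and 3' pairing. Features are combined
    with a linear model into a predicted repression score, convertible to
    oriented percentiles, and results are exportable as CSV and BED. Includes
    deterministic generators for synthetic UTRs with planted sites, simulated
    orthologous alignments on a phylogeny, and synthetic repression datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
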