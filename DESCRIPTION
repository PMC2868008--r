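Package: motifem
Title: Motif Discovery by Expectation Maximization with Position-Specific Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers ungapped sequence motifs in DNA or protein sequence sets
    with the three-phase MEME algorithm (starting-point search, expectation
    maximization under the OOPS and ZOOPS sequence models, and significance
    scoring via Hertz-Stormo column p-values and motif E-values), extended so
    that a position-specific prior over motif site locations can guide every
    phase. Includes width renormalization of priors, probabilistic erasing for
    multiple-motif discovery, motif quality metrics (scaled Euclidean
    inter-motif distance with alignment and strand search, average motif
    affinity, rank correlation, paired sign test), and a planted-motif
    synthetic data generator for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
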