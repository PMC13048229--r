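Package: msabench
Title: Benchmarking Multiple Sequence Alignment Tools with IUPAC Threshold Consensus
Version: 0.1.0
Authors@R:
    person("msabench", "developers", email = "msabench@example.org", role = c("aut", "cre"))
Description: Evaluates how well multiple sequence alignment (MSA) methods
    recover a reference sequence from noisy long-read segments. Builds
    per-column IUPAC threshold consensus sequences from MSAs, scores them
    against a (possibly diploid, IUPAC-encoded) reference with
    IUPAC-aware identity, match, ambiguity and error rates, and
    orchestrates benchmark grids over region sizes, sequencing depths,
    error profiles and MSA methods. Ships a read simulator with
    controlled substitution/insertion/deletion error profiles, an
    artificial diploid (heterozygous) reference builder, an exact global
    pairwise aligner and a center-star MSA heuristic so the whole
    pipeline runs without external binaries, plus adapters for external
    MSA tools and a metaconsensus combining their outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
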