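Package: indelfit
Title: Indel Length Distribution Selection for Multiple Sequence
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines which indel length distribution (truncated Zipf,
    geometric, or Poisson, each in a simple or rich variant) best fits a
    multiple sequence alignment and its rooted phylogeny. Provides a
    Gillespie-style insertion/deletion simulator along a tree, 27
    gap-pattern summary statistics, a learned correction for the bias an
    alignment program introduces into those statistics, rejection-based
    approximate Bayesian computation model selection using Mahalanobis
    distances, and posterior predictive adequacy tests that flag
    alignments no candidate model describes well.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
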