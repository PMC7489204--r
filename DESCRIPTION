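Package: SubMatBench
Title: Benchmarking Amino Acid Substitution Matrices on Simulated
    Divergent Evolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machinery for ranking amino-acid substitution matrices by the
    quality of the pairwise alignments they produce. Simulates pairs of
    protein sequences diverging from a common ancestor under the Dayhoff
    PAM point-substitution model with Zipf-distributed insertions and
    deletions, so that the true (reference) alignment is known by
    construction. Aligns the pairs with affine-gap Smith-Waterman and
    Needleman-Wunsch dynamic programming, scores the alignments against
    the reference with the Accuracy (I/R) and Confidence (I/A) measures,
    optimizes gap penalties over a grid, ranks matrices by their optimal
    quality, and compares matrices by Pearson correlation. Canonical
    PAM and BLOSUM tables are bundled; arbitrary matrices load from
    NCBI/EMBOSS square text format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
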