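Package: rngbench
Title: Randomness Measures and Classification Benchmarks for Human
    Random Number Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A battery of randomness measures for sequences produced in
    human random number generation (RNG) tasks -- the Towse & Neil
    collection of psychological indices (redundancy, RNG/RNG2, null-score
    quotient, coupon score, repetition gap, adjacency, turning point,
    runs, phi), rolling-window block entropy, and algorithmic-complexity
    measures (coding-theorem lookup means, the block decomposition
    method, Lempel-Ziv 1976 phrase counts, DEFLATE compressed length) --
    together with seedable generators of uniform and human-biased digit
    sequences and a bootstrapped logistic-regression benchmark that
    scores each measure's ability to separate human-generated from
    random sequences via out-of-bag correct classification rates with
    percentile confidence intervals and common language effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
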