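Package: mcrum
Title: Multiclass Relevance Units Machine with Error-Correcting Output Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse probabilistic kernel classification for multiclass
    problems. Binary classification relevance units machines (kernel
    logistic models over a small set of cluster-derived relevance units,
    with empirical-Bayes regularization) are combined under the
    error-correcting output codes framework using one-versus-rest,
    all-pairs, or random dense/sparse coding matrices. Class posterior
    probabilities are recovered by a linear-time naive product decoder or
    by the generalized Bradley-Terry model; hard nearest-codeword decoding
    is also provided. Includes K-means/AIC selection of model complexity
    and kernel width, k-mer featurization of small non-coding RNA
    sequences (miRNA/piRNA versus other ncRNA fragments), an ROC protocol
    with a rejection option, cross-validation helpers, and seeded
    synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
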