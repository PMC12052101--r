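Package: synnorm
Title: Frequency-Guided Synonym Normalization for Biomedical Corpus Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes tokenized biomedical text corpora by replacing
    infrequent non-biomedical words with their most frequent in-corpus
    synonym, and evaluates the effect of that normalization on word-embedding
    quality. Provides corpus and frequency-table utilities, a synonym-pool
    resource backed by a lexical-database export or fixture table, the
    replacement-plan builder and applicator, a seeded single-threaded
    skip-gram negative-sampling embedding trainer, concept-set (GMT) loading
    and filtering, intra-set pairwise cosine-distance coherence comparisons
    with paired t-tests, distribution diagnostics (ECDF, Q-Q,
    Kolmogorov-Smirnov), and a synthetic corpus generator with known synonym
    classes and concept sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
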