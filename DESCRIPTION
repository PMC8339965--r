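Package: elscore
Title: Automated Scoring of Child Expressive-Language Subtests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Item-level automated scoring of four child expressive-language
    subtests (expressive vocabulary, word structure, recalling sentences,
    formulated sentences) from prompt-response transcripts, followed by
    multi-tier aggregation of item scores into raw scores, age-normed scaled
    scores, and an Expressive Language Index composite. Includes a
    deterministic edit-distance scorer for sentence repetition, trainable
    item classifiers behind a common contract (a small trainable
    self-attention pair encoder, SVM and MLP baselines, and an n-gram
    nearest-profile model), a synthetic transcript generator with known gold
    scores, synthetic norm-table construction calibrated to scaled mean 10
    (SD 3) and composite mean 100 (SD 15), and a repeated k-fold
    cross-validation evaluation harness reporting accuracy, precision,
    recall, per-tier mean absolute error, and Spearman correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
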