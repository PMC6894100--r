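Package: lungnlp
Title: Rule-Based Extraction of Lung Cancer Data Elements from Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts six lung-cancer research data elements (overall stage,
    histological type, tumor grade, chemotherapy, radiotherapy and surgery)
    from collections of clinical narratives using a configurable
    regular-expression rule engine with exclusion contexts, normalizes raw
    mentions to canonical value sets, resolves discordant mentions by
    frequency with severity-aware tie-breaking, and combines results across
    document sources by a pathology-first priority. Includes a
    patient-level evaluation framework (coverage, two precisions and
    recall with hierarchical histology and stage matching), a synthetic
    EHR corpus generator with known gold labels for end-to-end testing,
    and a convolutional text classifier with word2vec-style embeddings
    used as an independent cross-check on histology extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    yaml,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
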