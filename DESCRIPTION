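Package: weatherlex
Title: Context-Sensitive Weather and Sentiment Lexicons from Geolocated Short Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Measures how weather affects expressed mood in geolocated
    short-text corpora. Implements a filtering cascade that reduces a raw
    thematic corpus to human-authored posts, joins each post to gridded daily
    weather and converts conditions to anomaly z-scores against a local
    reference climatology, induces corpus-specific sentiment and
    weather-severity token lexicons by label propagation over a PPMI
    word-association graph (with percentile tagging of extreme-weather posts
    as weighted seeds), scores posts with grammatical modifiers, and produces
    binned exposure-response curves, pairwise condition grids, word-level
    scatters and regionally normalized curve comparisons. Ships a synthetic
    corpus generator with known token loadings and mood response so that
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
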