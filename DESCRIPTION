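Package: clinner
Title: Nested Clinical Named-Entity Recognition and Concept Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for nested named-entity recognition and dictionary-based
    concept normalization in clinical text. Reads and writes BRAT standoff
    annotations and CoNLL-2003 token tables, encodes possibly nested entity
    mentions with the BMEWO-V tag scheme, tags sentences with a character-
    and sense-aware bidirectional LSTM-CRF sequence model trained by
    stochastic gradient descent, scores predictions with strict entity-level
    precision/recall/F1 and token-level confusion matrices, and links
    recognized mentions to concept identifiers by a two-stage dictionary
    search (bounded Levenshtein distance, then thresholded fuzzy similarity)
    with abbreviation expansion. Includes a seeded generator of synthetic
    annotated clinical corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
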