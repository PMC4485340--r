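Package: resner
Title: Recognition of Database and Software Name Mentions in Scientific Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating mentions of bioinformatics databases and
    software in scientific full text. Provides a dictionary baseline with
    leftmost-longest matching and abbreviation expansion, token-level feature
    extraction (shape, orthographic, lexical, dictionary and syntactic
    features) over a fixed context window, a linear-chain sequence tagger with
    B-I-O labels, a corpus-wide two-pass relabelling step that recovers
    mentions missed after their first occurrence, strict and lenient
    mention-level evaluation with k-fold cross-validation and feature
    ablation, descriptive analytics of resource-name composition, rule-based
    clue detectors (head terms, Hearst enumerations, title patterns, versions,
    references and comparisons), and a seeded generator of annotated synthetic
    corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
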