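Package: fonospell
Title: Hybrid String and Phonetic Matching of Misspelt Drug Names in
    Portuguese Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies misspelt mentions of drug names in free-text medical
    records written in Brazilian Portuguese by combining a normalized
    edit-distance string similarity with a language-dependent phonetic
    similarity computed from a grapheme-to-phoneme rule table. Provides
    consonantal-phoneme blocking for candidate generation, a joint
    (phonetic, string) threshold grid search tuned on labelled candidate
    pairs, construction of a misspelt-variant dictionary, a trie-indexed
    bounded-edit-distance fuzzy lookup for corpus-scale annotation, and a
    seeded misspelling simulator that generates labelled benchmarks with
    typographic, phonetic and concatenation errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
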