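# Candidate generation: blocking, the string-similarity pre-filter, and the
# joint-threshold match decision.

#' Generate candidate misspelt words for each drug
#'
#' Blocking step: for every drug name, keep the vocabulary words that share
#' at least `min_shared_consonants` consonantal phonemes (order-preserving)
#' with it, or lie within `max_edit_distance` edits of it. Both sides are
#' normalized and phonetically encoded; a drug never appears in its own
#' candidate list, and tokens shorter than `min_word_length` letters are
#' dropped because they match almost everything within 3 edits.
#'
#' @param drugs Character vector of canonical drug names.
#' @param vocab Character vector of corpus tokens (deduplicated internally).
#' @param min_shared_consonants Blocking threshold on matching consonantal
#'   phonemes (default 3).
#' @param max_edit_distance Blocking threshold on edit distance (default 3).
#' @param min_word_length Minimum normalized token length (default 4).
#' @param rules A rule table from [phonetic_rules()].
#' @return A tibble of candidate pairs with columns `drug`, `word`,
#'   `string_sim`, `phonetic_sim` and `label` (`"unk"`).
#' @export
#' @examples
#' generate_candidates("fluoxetina", c("fluoxetna", "aeiou", "paracetamol"))
generate_candidates <- function(drugs, vocab,
                                min_shared_consonants = 3,
                                max_edit_distance = 3,
                                min_word_length = 4,
                                rules = NULL) {
  rules <- rules %||% default_rules()
  drugs <- unique(pt_normalize(drugs))
  drugs <- drugs[drugs != ""]
  vocab <- unique(pt_normalize(vocab))
  vocab <- vocab[nchar(vocab) >= min_word_length]
  if (length(drugs) == 0 || length(vocab) == 0) {
    return(empty_candidates())
  }
  vocab_cons <- vapply(
    pt_consonants(vocab, rules),
    function(s) paste(PT_SYMBOL_ALIAS[s], collapse = ""), ""
  )
  out <- purrr::map(drugs, function(d) {
    words <- setdiff(vocab, d)
    keep_cons <- vocab_cons[match(words, vocab)]
    ed <- edit_distance_to(d, words)
    d_cons <- paste(PT_SYMBOL_ALIAS[pt_consonants(d, rules)[[1]]],
                    collapse = "")
    shared <- cpp_lcs_length(rep(d_cons, length(words)), keep_cons)
    keep <- shared >= min_shared_consonants | ed <= max_edit_distance
    words <- words[keep]
    tibble::tibble(
      drug = rep(d, length(words)),
      word = words,
      string_sim = sim_from_ed(ed[keep], nchar(d), nchar(words)),
      phonetic_sim = phonetic_similarity(rep(d, length(words)), words,
                                         rules = rules),
      label = rep("unk", length(words))
    )
  })
  dplyr::bind_rows(out)
}

empty_candidates <- function() {
  tibble::tibble(drug = character(), word = character(),
                 string_sim = numeric(), phonetic_sim = numeric(),
                 label = character())
}

#' Filter candidate pairs by string similarity
#'
#' The complementary pre-filter applied after blocking: keep pairs with
#' `string_sim >= min_string_sim`. The default 0.6 is deliberately low — it
#' keeps roughly half false candidates for manual labelling — and the
#' operation is idempotent.
#'
#' @param pairs A candidate-pair tibble (from [generate_candidates()] or
#'   [read_candidates()]).
#' @param min_string_sim Lower cutoff in \[0, 1\]; default 0.6.
#' @return The filtered tibble, input order preserved.
#' @export
filter_candidates <- function(pairs, min_string_sim = 0.6) {
  stopifnot(min_string_sim >= 0, min_string_sim <= 1)
  dplyr::filter(pairs, .data$string_sim >= min_string_sim)
}

#' Joint-threshold match decision
#'
#' A candidate is accepted as a misspelt variant only if it passes both the
#' phonetic and the string similarity cutoffs (inclusive).
#'
#' @param phonetic_sim,string_sim Numeric vectors of similarity scores.
#' @param thresholds A threshold pair: a list or one-row data frame with
#'   elements `phonetic` and `string`, each in \[0, 1\].
#' @return Logical vector of match decisions.
#' @export
#' @examples
#' is_match(0.9, 0.84, thresholds = list(phonetic = 0.844, string = 0.831))
is_match <- function(phonetic_sim, string_sim, thresholds) {
  thr <- as_threshold_pair(thresholds)
  phonetic_sim >= thr$phonetic & string_sim >= thr$string
}

#' Classify candidate pairs at a threshold pair
#'
#' Adds a logical `match` column to a candidate-pair tibble using
#' [is_match()].
#'
#' @inheritParams filter_candidates
#' @param thresholds A threshold pair (see [is_match()]).
#' @return The input tibble with a `match` column.
#' @export
classify_candidates <- function(pairs, thresholds) {
  dplyr::mutate(pairs, match = is_match(.data$phonetic_sim, .data$string_sim,
                                        thresholds))
}

as_threshold_pair <- function(thresholds) {
  if (inherits(thresholds, "threshold_fit")) thresholds <- thresholds$thresholds
  thr <- as.list(thresholds)[c("phonetic", "string")]
  if (anyNA(names(thr)) || !all(vapply(thr, is.numeric, TRUE))) {
    stop("`thresholds` must provide numeric elements `phonetic` and `string`",
         call. = FALSE)
  }
  stopifnot(thr$phonetic >= 0, thr$phonetic <= 1,
            thr$string >= 0, thr$string <= 1)
  thr
}

#' Read / write candidate-pair tables
#'
#' Candidate pairs are exchanged as UTF-8 TSV with columns `drug`, `word`,
#' `string_sim`, `phonetic_sim`, `label` (values `pos`, `neg` or `unk`).
#'
#' @param path File path.
#' @return `read_candidates()` returns the candidate tibble;
#'   `write_candidates()` returns `pairs` invisibly.
#' @export
read_candidates <- function(path) {
  pairs <- readr::read_tsv(path, col_types = readr::cols(
    drug = readr::col_character(), word = readr::col_character(),
    string_sim = readr::col_double(), phonetic_sim = readr::col_double(),
    label = readr::col_character()
  ))
  bad <- setdiff(unique(pairs$label), c("pos", "neg", "unk"))
  if (length(bad) > 0) {
    stop("invalid labels in candidate table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pairs
}

#' @rdname read_candidates
#' @inheritParams filter_candidates
#' @export
write_candidates <- function(pairs, path) {
  stopifnot(all(c("drug", "word", "string_sim", "phonetic_sim", "label")
                %in% names(pairs)))
  readr::write_tsv(pairs[c("drug", "word", "string_sim", "phonetic_sim",
                           "label")], path)
  invisible(pairs)
}
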