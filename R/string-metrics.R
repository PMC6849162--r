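# Edit distance and the normalized string / phonetic similarity scores.

# ç occupies two bytes in UTF-8; fold it to a private single-byte marker so
# byte-oriented code (the C++ trie) and character-oriented code agree on
# string length and distances.
fold_cedilla <- function(x) chartr("ç", "", x)
unfold_cedilla <- function(x) chartr("", "ç", x)

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming one word into the other. Transpositions are
#' not a primitive operation: an adjacent swap costs 2.
#'
#' @param w1,w2 Character vectors, recycled to a common length and compared
#'   element-wise.
#' @return Integer vector of distances.
#' @export
#' @examples
#' edit_distance("fluoxetina", c("dfluoxetina", "fluxoetina", "flxtina"))
edit_distance <- function(w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n)
  w2 <- rep_len(as.character(w2), n)
  vapply(seq_len(n), function(i) as.integer(adist(w1[i], w2[i])), integer(1))
}

# One-against-many edit distance (vectorized through adist's matrix form).
edit_distance_to <- function(word, vocab) {
  if (length(vocab) == 0) return(integer(0))
  as.integer(drop(adist(word, vocab)))
}

sim_from_ed <- function(ed, len1, len2) {
  denom <- pmax(len1, len2)
  out <- 1 - ed / denom
  out[denom == 0] <- NA_real_
  out
}

#' Normalized string similarity
#'
#' `1 - edit_distance(w1, w2) / max(nchar(w1), nchar(w2))`: a score in
#' \[0, 1\] that equals 1 only on identical words. Undefined (`NA`) when both
#' words are empty.
#'
#' @inheritParams edit_distance
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
#' @examples
#' string_similarity("fluoxetina", "dfluoxetina")
string_similarity <- function(w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n)
  w2 <- rep_len(as.character(w2), n)
  sim_from_ed(edit_distance(w1, w2), nchar(w1), nchar(w2))
}

#' Phonetic similarity
#'
#' The normalized string similarity applied to the two phoneme sequences:
#' symbol-level edit distance divided by the longer sequence, subtracted
#' from 1. Homophonous spellings (e.g. `cassa` / `caça`) therefore score
#' exactly 1. Undefined (`NA`) when a word encodes to an empty sequence.
#'
#' @inheritParams edit_distance
#' @param rules A rule table from [phonetic_rules()].
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
#' @examples
#' phonetic_similarity("cassa", "caça")
phonetic_similarity <- function(w1, w2, rules = NULL) {
  rules <- rules %||% default_rules()
  n <- max(length(w1), length(w2))
  w1 <- pt_normalize(rep_len(as.character(w1), n))
  w2 <- pt_normalize(rep_len(as.character(w2), n))
  cache <- if (identical(rules, the$rules)) encode_cache() else NULL
  k1 <- vapply(w1, phoneme_key1, "", rules = rules, cache = cache,
               USE.NAMES = FALSE)
  k2 <- vapply(w2, phoneme_key1, "", rules = rules, cache = cache,
               USE.NAMES = FALSE)
  out <- sim_from_ed(edit_distance(k1, k2), nchar(k1), nchar(k2))
  out[nchar(k1) == 0 | nchar(k2) == 0] <- NA_real_ # empty encoding: undefined
  out
}

# Phonetic keys for a word vector, memoised across calls (default rules only).
phoneme_keys <- function(words, rules) {
  cache <- if (identical(rules, the$rules)) encode_cache() else NULL
  vapply(words, phoneme_key1, "", rules = rules, cache = cache,
         USE.NAMES = FALSE)
}
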