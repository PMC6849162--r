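# Brazilian-Portuguese grapheme-to-phoneme encoding.
#
# The encoder is table-driven: an ordered list of (pattern, prev, next,
# phonemes) rules scanned left-to-right over the normalized word, first match
# wins. The shipped table collapses the common homophone classes of Brazilian
# Portuguese orthography (ss/ç/ce-ci, intervocalic s/z, ch/x, que-qui/k,
# silent h) onto shared symbols, which is what makes the phonetic similarity
# tolerant to phonetic misspellings.

PT_VOWEL_SYMBOLS <- c("A", "E", "I", "O", "U")

# Internal single-character aliases for multi-character phoneme symbols, so
# symbol sequences can be compared with character-level edit distance.
PT_SYMBOL_ALIAS <- c(
  A = "A", E = "E", I = "I", O = "O", U = "U",
  B = "B", D = "D", F = "F", G = "G", J = "J", K = "K", L = "L",
  M = "M", N = "N", P = "P", R = "R", S = "S", T = "T", V = "V", Z = "Z",
  SH = "1", LH = "2", NH = "3", RR = "4"
)

the <- new.env(parent = emptyenv())

#' Load a grapheme-to-phoneme rule table
#'
#' Reads an ordered rule table mapping letter patterns (in context) to
#' phoneme symbols. The package ships a versioned table for Brazilian
#' Portuguese; supply `path` to override it, e.g. to experiment with a
#' different phoneme inventory.
#'
#' @param path Path to a tab-separated rule file with columns `pattern`,
#'   `prev`, `next`, `phonemes`. `prev`/`next` are single-character regular
#'   expressions matched against the neighbouring letter (`_` = word
#'   boundary, empty = any); `phonemes` is a space-separated list of emitted
#'   symbols, `-` meaning silent. Lines starting with `#` are comments.
#'   `NULL` (default) loads the packaged Brazilian-Portuguese table.
#' @return A tibble with one row per rule, in application order.
#' @export
#' @examples
#' phonetic_rules()
phonetic_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phonetic_rules_pt.tsv", package = "fonospell")
  }
  rules <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  stopifnot(all(c("pattern", "prev", "next", "phonemes") %in% names(rules)))
  rules
}

default_rules <- function() {
  if (is.null(the$rules)) the$rules <- phonetic_rules()
  the$rules
}

# Accent-folding map: every accented vowel to its base letter; ç is kept as a
# letter of its own because the rule table needs it.
PT_ACCENT_FROM <- "áàâãäéèêëíìîïóòôõöúùûü"
PT_ACCENT_TO <- "aaaaaeeeeiiiiooooouuuu"

#' Normalize a raw token for matching
#'
#' Lower-cases, strips diacritics (keeping `ç`, which carries phonetic
#' information used by the rule table) and removes every character that is
#' not a Portuguese letter.
#'
#' @param word Character vector of raw tokens.
#' @param strict If `TRUE`, signal an error when a token is empty after
#'   normalization; otherwise such tokens become `""`.
#' @return Character vector of normalized words (lowercase `a`-`z` plus `ç`).
#' @export
#' @examples
#' pt_normalize(c("Fluoxetina", "INSULINA", "coracao"))
pt_normalize <- function(word, strict = FALSE) {
  x <- stringr::str_to_lower(as.character(word), locale = "pt")
  x <- chartr(PT_ACCENT_FROM, PT_ACCENT_TO, x)
  x <- stringr::str_remove_all(x, "[^a-zç]")
  if (strict && any(x == "" | is.na(x))) {
    stop("token empty after normalization", call. = FALSE)
  }
  x[is.na(x)] <- ""
  x
}

# Encode one normalized word; returns character vector of phoneme symbols.
encode1 <- function(word, rules) {
  if (is.na(word) || word == "") return(character())
  # collapse doubled letters other than r/s (rr and ss carry their own rules)
  word <- gsub("([^rs])\\1+", "\\1", word)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pat <- rules$pattern
  plen <- nchar(pat)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- FALSE
    for (r in seq_along(pat)) {
      w <- plen[r]
      if (i + w - 1L > n) next
      if (substr(word, i, i + w - 1L) != pat[r]) next
      prev_re <- rules$prev[r]
      if (prev_re != "") {
        prev_ch <- if (i == 1L) "_" else chars[i - 1L]
        if (!grepl(prev_re, prev_ch)) next
      }
      next_re <- rules[["next"]][r]
      if (next_re != "") {
        next_ch <- if (i + w - 1L >= n) "_" else chars[i + w]
        if (!grepl(next_re, next_ch)) next
      }
      emit <- rules$phonemes[r]
      if (emit != "-") out <- c(out, strsplit(emit, " ", fixed = TRUE)[[1]])
      i <- i + w
      hit <- TRUE
      break
    }
    if (!hit) i <- i + 1L # letter with no rule: skip (closed-table default)
  }
  out
}

# Memoised symbol-alias string for a normalized word (used by every metric).
phoneme_key1 <- function(word, rules, cache = NULL) {
  if (is.na(word) || word == "") return("")
  if (!is.null(cache)) {
    hit <- cache[[word]]
    if (!is.null(hit)) return(hit)
  }
  key <- paste(PT_SYMBOL_ALIAS[encode1(word, rules)], collapse = "")
  if (!is.null(cache) && word != "") cache[[word]] <- key
  key
}

encode_cache <- function() {
  if (is.null(the$cache)) the$cache <- new.env(parent = emptyenv())
  the$cache
}

#' Encode words as phoneme sequences
#'
#' Applies the grapheme-to-phoneme rule table to each word (after
#' [pt_normalize()]) and returns one row per emitted phoneme symbol.
#' Encoding is a pure function of the input word and the rule table.
#'
#' @param word Character vector of words (raw tokens are normalized first).
#' @param rules A rule table from [phonetic_rules()]; defaults to the
#'   packaged Brazilian-Portuguese table.
#' @return A tibble with columns `word` (the input), `position`, `symbol`
#'   and `consonantal` (logical). Words that are empty after normalization
#'   contribute no rows.
#' @export
#' @examples
#' pt_encode(c("hora", "ora", "cassa", "caça"))
pt_encode <- function(word, rules = NULL) {
  rules <- rules %||% default_rules()
  norm <- pt_normalize(word)
  seqs <- lapply(norm, encode1, rules = rules)
  tibble::tibble(
    word = rep(as.character(word), lengths(seqs)),
    position = unlist(lapply(lengths(seqs), seq_len), use.names = FALSE),
    symbol = unlist(seqs, use.names = FALSE) %||% character()
  ) |>
    dplyr::mutate(consonantal = !(.data$symbol %in% PT_VOWEL_SYMBOLS))
}

#' Consonantal phoneme subsequence of each word
#'
#' The ordered consonantal symbols of the phonetic encoding, used for cheap
#' candidate blocking.
#'
#' @inheritParams pt_encode
#' @return A list (one element per input word) of character vectors of
#'   consonantal phoneme symbols.
#' @export
#' @examples
#' pt_consonants(c("fluoxetina", "aeiou"))
pt_consonants <- function(word, rules = NULL) {
  rules <- rules %||% default_rules()
  norm <- pt_normalize(word)
  lapply(norm, function(w) {
    s <- encode1(w, rules)
    s[!(s %in% PT_VOWEL_SYMBOLS)]
  })
}

#' Count matching consonantal phonemes between two words
#'
#' The length of the longest common subsequence of the two consonantal
#' phoneme sequences (order-preserving, so anagrams do not inflate the
#' count). Set `method = "multiset"` to count shared symbols regardless of
#' order instead.
#'
#' @param w1,w2 Character vectors of words, recycled to a common length.
#' @param rules A rule table from [phonetic_rules()].
#' @param method `"lcs"` (default) or `"multiset"`.
#' @return Integer vector of matching-consonant counts; symmetric in
#'   `w1`/`w2` and bounded by the shorter consonant sequence.
#' @export
#' @examples
#' consonant_match_count("paracetamol", "parasetamol")
consonant_match_count <- function(w1, w2, rules = NULL,
                                  method = c("lcs", "multiset")) {
  method <- match.arg(method)
  rules <- rules %||% default_rules()
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n)
  w2 <- rep_len(as.character(w2), n)
  c1 <- pt_consonants(w1, rules)
  c2 <- pt_consonants(w2, rules)
  if (method == "multiset") {
    return(vapply(seq_len(n), function(i) {
      t1 <- table(c1[[i]])
      t2 <- table(c2[[i]])
      shared <- intersect(names(t1), names(t2))
      as.integer(sum(pmin(t1[shared], t2[shared])))
    }, integer(1)))
  }
  a <- vapply(c1, function(s) paste(PT_SYMBOL_ALIAS[s], collapse = ""), "")
  b <- vapply(c2, function(s) paste(PT_SYMBOL_ALIAS[s], collapse = ""), "")
  cpp_lcs_length(a, b)
}

#' Phonetic key of a word
#'
#' Space-separated phoneme symbols, convenient for display and exact
#' phonetic-key grouping.
#'
#' @inheritParams pt_encode
#' @return Character vector of phoneme strings, e.g. `"F L U O K S E T I N A"`.
#' @export
#' @examples
#' pt_phoneme_key("fluoxetina")
pt_phoneme_key <- function(word, rules = NULL) {
  rules <- rules %||% default_rules()
  norm <- pt_normalize(word)
  vapply(norm, function(w) paste(encode1(w, rules), collapse = " "), "",
         USE.NAMES = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
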