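# Trie-backed fuzzy dictionary index.

#' Build a fuzzy dictionary index
#'
#' Indexes a variant dictionary (misspelt surface form to canonical drug
#' name) in a trie so that all entries within a small edit distance of a
#' query can be retrieved without scanning the whole dictionary.
#'
#' @param dictionary Either a data frame with columns `variant` and
#'   `canonical` (extra columns are ignored), or a character vector of
#'   dictionary words, optionally named by their canonical form (unnamed
#'   words are their own canonical form).
#' @return A `fuzzy_index` object.
#' @export
#' @examples
#' idx <- fuzzy_index(c(fluoxetina = "fluoxetina", fluoxetna = "fluoxetina"))
#' fuzzy_lookup(idx, "fluoxetnas", max_ed = 1)
fuzzy_index <- function(dictionary) {
  if (is.data.frame(dictionary)) {
    stopifnot(all(c("variant", "canonical") %in% names(dictionary)))
    variant <- as.character(dictionary$variant)
    canonical <- as.character(dictionary$canonical)
  } else {
    canonical <- as.character(dictionary)
    variant <- names(dictionary) %||% canonical
    variant[variant == ""] <- canonical[variant == ""]
    # conventional direction: names(x) = variants, values = canonicals;
    # for a bare vector each word is its own canonical form
    if (is.null(names(dictionary))) canonical <- variant
  }
  if (anyNA(variant) || any(variant == "")) {
    stop("dictionary entries must be non-empty words", call. = FALSE)
  }
  dup <- duplicated(variant)
  if (any(dup)) {
    clash <- tapply(canonical, variant, function(x) length(unique(x)) > 1L)
    if (any(clash)) {
      stop("duplicate dictionary keys with conflicting canonical names: ",
           paste(head(names(clash)[clash], 5), collapse = ", "),
           call. = FALSE)
    }
    variant <- variant[!dup]
    canonical <- canonical[!dup]
  }
  idx <- new.env(parent = emptyenv())
  idx$variant <- variant
  idx$canonical <- canonical
  idx$ptr <- cpp_trie_build(fold_cedilla(variant))
  class(idx) <- "fuzzy_index"
  idx
}

index_ptr <- function(index) {
  # external pointers do not survive serialization; rebuild lazily
  if (is.null(index$ptr) || !cpp_ptr_valid(index$ptr)) {
    index$ptr <- cpp_trie_build(fold_cedilla(index$variant))
  }
  index$ptr
}

#' Enumerate a fuzzy index
#'
#' Walks the trie and returns every stored word; round-trips exactly with
#' the dictionary the index was built from.
#'
#' @param index A [fuzzy_index()].
#' @return Character vector of dictionary words in lexicographic order of
#'   the trie walk.
#' @export
enumerate_index <- function(index) {
  stopifnot(inherits(index, "fuzzy_index"))
  unfold_cedilla(cpp_trie_enumerate(index_ptr(index)))
}

#' Bounded-edit-distance dictionary lookup
#'
#' Returns every dictionary entry within `max_ed` edits of each query, with
#' its exact distance, by propagating the edit-distance computation down the
#' trie and pruning branches that can no longer stay within the bound.
#'
#' @param index A [fuzzy_index()].
#' @param query Character vector of (normalized) query words.
#' @param max_ed Maximum edit distance, between 0 and 3. Lookups are fast
#'   for `max_ed <= 1`, the bound used for corpus annotation; a warning is
#'   issued above 2 because cost grows steeply with the bound.
#' @return A tibble with columns `query`, `entry` (the dictionary word),
#'   `canonical` and `distance`, sorted by query, then distance, then entry.
#' @export
#' @examples
#' idx <- fuzzy_index("fluoxetina")
#' fuzzy_lookup(idx, c("fluoxetna", "fluxoetina"), max_ed = 1)
fuzzy_lookup <- function(index, query, max_ed = 1) {
  stopifnot(inherits(index, "fuzzy_index"))
  max_ed <- as.integer(max_ed)
  stopifnot(length(max_ed) == 1, max_ed >= 0, max_ed <= 3)
  if (max_ed > 2) {
    warning("fuzzy lookup cost grows steeply beyond max_ed = 2", call. = FALSE)
  }
  query <- as.character(query)
  hits <- cpp_fuzzy_lookup(index_ptr(index), fold_cedilla(query), max_ed)
  tibble::tibble(
    query = query[hits$query],
    entry = index$variant[hits$entry],
    canonical = index$canonical[hits$entry],
    distance = as.integer(hits$distance)
  ) |>
    dplyr::arrange(match(.data$query, query), .data$distance, .data$entry)
}

#' @export
print.fuzzy_index <- function(x, ...) {
  cat("<fuzzy_index> ", length(x$variant), " entries, ",
      length(unique(x$canonical)), " canonical names\n", sep = "")
  invisible(x)
}

#' @export
length.fuzzy_index <- function(x) length(x$variant)
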