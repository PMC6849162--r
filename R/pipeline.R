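# End-to-end annotation: tokenization, fuzzy-index annotation of documents,
# and span-level evaluation. Documents and annotations travel as JSONL.

#' Tokenize document text
#'
#' Tokens are maximal runs of letters (including accented letters and `ç`);
#' everything else separates tokens. Offsets are 0-based half-open character
#' positions into the original text.
#'
#' @param text Character vector of document texts.
#' @return A tibble with columns `doc` (index into `text`), `start`, `end`,
#'   `token`.
#' @export
#' @examples
#' tokenize_text("tomando fluoxetna 20mg")
tokenize_text <- function(text) {
  text <- as.character(text)
  loc <- stringr::str_locate_all(text, "\\p{L}+")
  purrr::map2(seq_along(text), loc, function(i, m) {
    tibble::tibble(
      doc = i,
      start = as.integer(m[, "start"] - 1L),
      end = as.integer(m[, "end"]),
      token = stringr::str_sub(text[i], m[, "start"], m[, "end"])
    )
  }) |> dplyr::bind_rows()
}

#' Read a drug lexicon
#'
#' UTF-8 plain text, one canonical name per line; names are normalized and
#' deduplicated, and empty lines dropped.
#'
#' @param path File path.
#' @return Character vector of normalized drug names.
#' @export
read_lexicon <- function(path) {
  x <- pt_normalize(readLines(path, encoding = "UTF-8"))
  unique(x[x != ""])
}

#' Annotate drug mentions in documents
#'
#' Builds a fuzzy index over the canonical lexicon plus an optional variant
#' dictionary and annotates every token that lies within `max_ed` edits of
#' an indexed entry. Exact canonical mentions resolve at distance 0. When a
#' token matches several entries, the minimum-distance match wins, ties
#' broken lexicographically by canonical name (and counted in the summary
#' written to standard error).
#'
#' @param documents A data frame with columns `doc_id` and `text`.
#' @param lexicon Character vector of canonical drug names.
#' @param variants Optional variant dictionary (tibble with `variant`,
#'   `canonical`) from [build_variant_dictionary()].
#' @param max_ed Edit-distance bound for the fuzzy lookup (default 1).
#' @param min_token_length Tokens shorter than this (after normalization)
#'   are never matched (default 4).
#' @param quiet Suppress the per-run summary on standard error.
#' @return A tibble of annotations: `doc_id`, `start`, `end`, `surface`,
#'   `canonical`, `variant` (the dictionary entry matched), `distance`.
#' @export
#' @examples
#' docs <- tibble::tibble(doc_id = "d1", text = "tomando fluoxetna 20mg")
#' annotate_documents(docs, lexicon = "fluoxetina", quiet = TRUE)
annotate_documents <- function(documents, lexicon, variants = NULL,
                               max_ed = 1, min_token_length = 4,
                               quiet = FALSE) {
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  lexicon <- unique(pt_normalize(lexicon))
  lexicon <- lexicon[lexicon != ""]
  dict <- tibble::tibble(variant = lexicon, canonical = lexicon)
  if (!is.null(variants)) {
    dict <- dplyr::bind_rows(dict, variants[c("variant", "canonical")]) |>
      dplyr::distinct(.data$variant, .keep_all = TRUE)
  }
  index <- fuzzy_index(dict)

  if (nrow(documents) == 0) return(empty_annotations())
  toks <- tokenize_text(documents$text)
  if (nrow(toks) == 0) return(empty_annotations())
  toks$doc_id <- documents$doc_id[toks$doc]
  toks$norm <- pt_normalize(toks$token)
  toks <- toks[nchar(toks$norm) >= min_token_length, ]
  if (nrow(toks) == 0) return(empty_annotations())

  uniq <- unique(toks$norm)
  hits <- fuzzy_lookup(index, uniq, max_ed = max_ed)
  n_tied <- 0L
  best <- hits |>
    dplyr::group_by(.data$query) |>
    dplyr::arrange(.data$distance, .data$canonical, .data$entry,
                   .by_group = TRUE) |>
    dplyr::summarise(
      entry = .data$entry[1], canonical = .data$canonical[1],
      distance = .data$distance[1],
      tied = sum(.data$distance == .data$distance[1]) > 1L
    )
  n_tied <- sum(best$tied)

  ann <- dplyr::inner_join(toks, best, by = c(norm = "query")) |>
    dplyr::transmute(
      doc_id = .data$doc_id, start = .data$start, end = .data$end,
      surface = .data$token, canonical = .data$canonical,
      variant = .data$entry, distance = as.integer(.data$distance)
    ) |>
    dplyr::arrange(match(.data$doc_id, documents$doc_id), .data$start)
  if (!quiet) {
    message(sprintf(
      "annotate: %d documents, %d tokens, %d matches, %d tied tokens",
      nrow(documents), nrow(toks), nrow(ann), n_tied
    ))
  }
  ann
}

empty_annotations <- function() {
  tibble::tibble(doc_id = character(), start = integer(), end = integer(),
                 surface = character(), canonical = character(),
                 variant = character(), distance = integer())
}

#' Evaluate predicted annotations against gold mentions
#'
#' A prediction is a true positive iff its `(doc_id, start, end, canonical)`
#' matches a gold mention exactly. Duplicate predictions on one span are
#' invalid input.
#'
#' @param pred,gold Annotation tibbles with columns `doc_id`, `start`,
#'   `end`, `canonical`.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_annotations <- function(pred, gold) {
  need <- c("doc_id", "start", "end", "canonical")
  stopifnot(all(need %in% names(pred)), all(need %in% names(gold)))
  span <- function(d) paste(d$doc_id, d$start, d$end, sep = "\r")
  if (anyDuplicated(span(pred)) > 0) {
    stop("duplicate predictions on one token span", call. = FALSE)
  }
  key <- function(d) paste(d$doc_id, d$start, d$end, d$canonical, sep = "\r")
  tp <- sum(key(pred) %in% key(gold))
  confusion_row(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

#' Read and write JSONL tables
#'
#' One JSON object per line; used for documents, gold mentions and
#' annotations.
#'
#' @param x A data frame.
#' @param path File path (or an open connection for `write_jsonl()`).
#' @return `read_jsonl()` returns a tibble; `write_jsonl()` returns `x`
#'   invisibly.
#' @export
write_jsonl <- function(x, path) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
  }
  if (nrow(x) > 0) {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      jsonlite::toJSON(as.list(x[i, ]), auto_unbox = TRUE, digits = NA,
                       na = "null")
    }, "")
    writeLines(lines, con)
  }
  invisible(x)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(tibble::tibble())
  purrr::map(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    obj[vapply(obj, is.null, logical(1))] <- NA
    tibble::as_tibble(obj)
  }) |> dplyr::bind_rows()
}
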