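# Seeded generator of synthetic misspelt drug-name variants, decoys and
# small documents with gold mention offsets. This is the package's stand-in
# for labelled clinical data: every variant carries its generating class and
# edit budget, so downstream tuning/search/annotation can be scored exactly.

TYPO_ALPHABET <- letters

#' Packaged drug and filler lexicons
#'
#' `example_drugs()` returns the 20 most-cited drug names of the reference
#' corpus (with occurrence counts); `filler_words()` returns a small lexicon
#' of common Portuguese clinical-note words used as decoys and document
#' filler.
#'
#' @return `example_drugs()`: a tibble with `drug` and `occurrences`;
#'   `filler_words()`: a character vector.
#' @export
example_drugs <- function() {
  readr::read_tsv(
    system.file("extdata", "drug_names_pt.tsv", package = "fonospell"),
    col_types = readr::cols(drug = readr::col_character(),
                            occurrences = readr::col_integer())
  )
}

#' @rdname example_drugs
#' @export
filler_words <- function() {
  readLines(system.file("extdata", "filler_words_pt.txt",
                        package = "fonospell"), encoding = "UTF-8")
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# --- single-variant generators (operate on the current RNG stream) --------

typo_once <- function(base, budget) {
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ops <- c("insert", "delete", "substitute")
  if (budget >= 2 && n >= 2) ops <- c(ops, "swap")
  if (n <= 4) ops <- setdiff(ops, "delete")
  op <- sample(ops, 1)
  cost <- 1L
  if (op == "insert") {
    pos <- sample(0:n, 1)
    chars <- append(chars, sample(TYPO_ALPHABET, 1), after = pos)
  } else if (op == "delete") {
    chars <- chars[-sample(n, 1)]
  } else if (op == "substitute") {
    pos <- sample(n, 1)
    chars[pos] <- sample(setdiff(TYPO_ALPHABET, chars[pos]), 1)
  } else { # adjacent swap; costs two unit edits
    ok <- which(chars[-n] != chars[-1])
    pos <- if (length(ok) > 0) ok[sample(length(ok), 1)] else sample(n - 1, 1)
    chars[c(pos, pos + 1)] <- chars[c(pos + 1, pos)]
    cost <- 2L
  }
  list(word = paste(chars, collapse = ""), cost = cost)
}

typo_impl <- function(base, n_edits) {
  for (attempt in 1:25) {
    word <- base
    spent <- 0L
    while (spent < n_edits) {
      step <- typo_once(word, n_edits - spent)
      word <- step$word
      spent <- spent + step$cost
    }
    if (word != base) break
  }
  tibble::tibble(base = base, surface = word, label = "positive-typo",
                 n_edits = as.integer(n_edits))
}

# Candidate homophone substitution sites under the packaged rule table.
# Each site is (start, length, replacement); applying any of them leaves the
# phonetic encoding unchanged. Near-homophone vowel swaps are a separate,
# weaker class.
homophone_sites <- function(word, include_near = FALSE) {
  sites <- list()
  add <- function(start, len, repl) {
    sites[[length(sites) + 1]] <<- list(start = start, len = len, repl = repl)
  }
  n <- nchar(word)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  vowel <- ch %in% c("a", "e", "i", "o", "u")
  # silent h: removable if leading, insertable otherwise
  if (ch[1] == "h") add(1, 1, "") else add(1, 0, "h")
  for (i in seq_len(n)) {
    nxt <- if (i < n) ch[i + 1] else "#"
    prv <- if (i > 1) ch[i - 1] else "#"
    two <- if (i < n) paste0(ch[i], ch[i + 1]) else ""
    if (two == "ss") {
      if (nxt_of(ch, i + 1) %in% c("a", "o", "u")) add(i, 2, "ç")
      if (nxt_of(ch, i + 1) %in% c("e", "i")) add(i, 2, "c")
    }
    if (ch[i] == "ç") add(i, 1, "ss")
    if (ch[i] == "c" && nxt %in% c("e", "i")) add(i, 1, "ss")
    if (ch[i] == "z" && i > 1 && i < n && vowel[i - 1] && vowel[i + 1]) {
      add(i, 1, "s")
    }
    if (ch[i] == "s" && i > 1 && i < n && vowel[i - 1] && vowel[i + 1]) {
      add(i, 1, "z")
    }
    if (two == "ch" && (i == 1 || !vowel[i - 1])) add(i, 2, "x")
    if (ch[i] == "x" && (i == 1 || !vowel[i - 1]) &&
        !(i > 1 && i < n && vowel[i - 1] && vowel[i + 1])) {
      add(i, 1, "ch")
    }
    if (two == "qu" && nxt_of(ch, i + 1) %in% c("e", "i")) add(i, 2, "k")
    if (ch[i] == "k" && nxt %in% c("e", "i")) add(i, 1, "qu")
    if (include_near && vowel[i] && i == n) {
      swap <- c(a = NA, e = "i", i = "e", o = "u", u = "o")[ch[i]]
      if (!is.na(swap)) add(i, 1, unname(swap))
    }
  }
  sites
}

nxt_of <- function(ch, i) if (i + 1 <= length(ch)) ch[i + 1] else "#"

apply_site <- function(word, site) {
  if (site$len == 0) {
    paste0(site$repl, word)
  } else {
    paste0(substr(word, 1, site$start - 1), site$repl,
           substr(word, site$start + site$len, nchar(word)))
  }
}

phonetic_impl <- function(base, include_near = FALSE) {
  sites <- homophone_sites(base, include_near = include_near)
  if (length(sites) == 0) {
    stop("no applicable homophone substitution site in '", base, "'",
         call. = FALSE)
  }
  site <- sites[[sample(length(sites), 1)]]
  exact <- site$len != 1 || !(site$repl %in% c("a", "e", "i", "o", "u"))
  tibble::tibble(
    base = base, surface = apply_site(base, site),
    label = if (exact) "positive-phonetic" else "positive-phonetic-near",
    n_edits = NA_integer_
  )
}

CONCAT_SUFFIXES <- c("por", "para", "ate")

concat_impl <- function(base) {
  suffix <- sample(CONCAT_SUFFIXES, 1)
  tibble::tibble(base = base, surface = paste0(base, suffix),
                 label = "positive-concatenation",
                 n_edits = as.integer(nchar(suffix)))
}

#' Simulate a single misspelt variant
#'
#' `typo_variant()` applies `n_edits` worth of random character edits
#' (insert / delete / substitute / adjacent swap, a swap counting as two
#' unit edits so that `edit_distance(base, surface) <= n_edits` always
#' holds). `phonetic_variant()` applies one homophone-class substitution
#' from the rule-table invariance classes, so the phonetic encoding — and
#' hence [phonetic_similarity()] — is unchanged; it signals an error when
#' the base offers no applicable site and `include_near = FALSE` excludes
#' the near-homophone final-vowel swaps. `concat_variant()` appends a short
#' function word, emulating run-together tokens.
#'
#' @param base Canonical drug name (normalized internally; at least 4
#'   letters for typos).
#' @param n_edits Edit budget, >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @param include_near Also allow near-homophone vowel substitutions
#'   (flagged with label `positive-phonetic-near`).
#' @return A one-row tibble with `base`, `surface`, `label`, `n_edits`.
#' @export
#' @examples
#' typo_variant("fluoxetina", n_edits = 1, seed = 1)
#' phonetic_variant("glicose", seed = 1)
typo_variant <- function(base, n_edits = 1, seed = NULL) {
  base <- pt_normalize(base, strict = TRUE)
  stopifnot(length(base) == 1, n_edits >= 1, nchar(base) >= 4)
  with_optional_seed(seed, typo_impl(base, as.integer(n_edits)))
}

#' @rdname typo_variant
#' @export
phonetic_variant <- function(base, seed = NULL, include_near = FALSE) {
  base <- pt_normalize(base, strict = TRUE)
  stopifnot(length(base) == 1)
  with_optional_seed(seed, phonetic_impl(base, include_near = include_near))
}

#' @rdname typo_variant
#' @export
concat_variant <- function(base, seed = NULL) {
  base <- pt_normalize(base, strict = TRUE)
  stopifnot(length(base) == 1)
  with_optional_seed(seed, concat_impl(base))
}

DERIVATIVE_SUFFIXES <- c("izando", "izacao")

derivative_decoy <- function(drug) {
  stem <- sub("[aeiou]+$", "", drug)
  paste0(stem, sample(DERIVATIVE_SUFFIXES, 1))
}

#' Generate a labelled misspelling benchmark
#'
#' For each drug, draws positive variants from a mixture of typographic,
#' phonetic and concatenation error classes, and negative decoys from other
#' drug names, a Portuguese filler lexicon and verbal derivatives of the
#' drug itself (the `insulinizar` phenomenon). Also emits small synthetic
#' documents that embed every positive variant at a known character offset,
#' plus decoy-only documents, for end-to-end annotation tests. The entire
#' benchmark is a deterministic function of `seed`.
#'
#' @param drugs Character vector of canonical drug names (default: the
#'   packaged 20-drug list).
#' @param n_pos_per_drug,n_neg_per_drug Positives / negatives per drug
#'   (each >= 1).
#' @param seed Integer seed (required).
#' @param mixture Named numeric mixture over classes `typo`, `phonetic`,
#'   `concat`; default 50/30/20.
#' @param p_two_edits Probability that a typo variant uses a 2-edit budget
#'   rather than 1 (default 0.3; single-edit errors dominate observed
#'   misspelling lists).
#' @return A `drug_benchmark` object: list with tibbles `pairs` (candidate
#'   pairs with `label` pos/neg and generator columns `class`, `n_edits`),
#'   `documents` (`doc_id`, `text`) and `mentions` (gold annotations with
#'   0-based half-open offsets).
#' @export
#' @examples
#' bench <- make_benchmark(c("fluoxetina", "glicose"), 3, 3, seed = 42)
#' bench$pairs
make_benchmark <- function(drugs = example_drugs()$drug,
                           n_pos_per_drug, n_neg_per_drug, seed,
                           mixture = c(typo = 0.5, phonetic = 0.3,
                                       concat = 0.2),
                           p_two_edits = 0.3) {
  stopifnot(n_pos_per_drug >= 1, n_neg_per_drug >= 1)
  drugs <- unique(pt_normalize(drugs, strict = TRUE))
  mixture <- mixture[c("typo", "phonetic", "concat")]
  stopifnot(!anyNA(mixture), all(mixture >= 0), sum(mixture) > 0)
  fillers <- setdiff(pt_normalize(filler_words()), drugs)

  withr::with_seed(seed, {
    variants <- purrr::map(drugs, function(d) {
      cls <- sample(names(mixture), n_pos_per_drug, replace = TRUE,
                    prob = mixture)
      pos <- purrr::map(cls, function(cl) {
        for (attempt in 1:25) {
          v <- switch(cl,
            typo = typo_impl(d, 1L + stats::rbinom(1, 1, p_two_edits)),
            phonetic = phonetic_impl(d),
            concat = concat_impl(d)
          )
          if (!(v$surface %in% drugs)) break
        }
        v
      }) |> dplyr::bind_rows()

      neg_cls <- sample(c("drug", "filler", "derivative"), n_neg_per_drug,
                        replace = TRUE, prob = c(0.5, 0.3, 0.2))
      neg_word <- vapply(neg_cls, function(cl) {
        switch(cl,
          drug = sample(setdiff(drugs, d), 1),
          filler = sample(fillers, 1),
          derivative = derivative_decoy(d)
        )
      }, "")
      neg <- tibble::tibble(base = d, surface = unname(neg_word),
                            label = paste0("negative-", neg_cls),
                            n_edits = NA_integer_)
      dplyr::bind_rows(pos, neg)
    }) |> dplyr::bind_rows()

    variants <- dplyr::distinct(variants, .data$base, .data$surface,
                                .keep_all = TRUE)
    pairs <- tibble::tibble(
      drug = variants$base,
      word = variants$surface,
      string_sim = string_similarity(variants$base, variants$surface),
      phonetic_sim = phonetic_similarity(variants$base, variants$surface),
      label = ifelse(startsWith(variants$label, "positive"), "pos", "neg"),
      class = variants$label,
      n_edits = variants$n_edits
    )

    embed <- variants[startsWith(variants$label, "positive") |
                        variants$label == "negative-derivative", ]
    docs <- purrr::map(seq_len(nrow(embed)), function(i) {
      pre <- sample(fillers, sample(3:6, 1))
      post <- sample(fillers, sample(2:4, 1))
      text <- paste(c(pre, embed$surface[i], post), collapse = " ")
      start <- sum(nchar(pre)) + length(pre) # 0-based: words + spaces before
      list(
        doc = tibble::tibble(doc_id = sprintf("doc%04d", i), text = text),
        mention = if (startsWith(embed$label[i], "positive")) {
          tibble::tibble(
            doc_id = sprintf("doc%04d", i),
            start = start, end = start + nchar(embed$surface[i]),
            surface = embed$surface[i], canonical = embed$base[i],
            class = embed$label[i], n_edits = embed$n_edits[i]
          )
        }
      )
    })
    bench <- list(
      pairs = pairs,
      documents = dplyr::bind_rows(purrr::map(docs, "doc")),
      mentions = dplyr::bind_rows(purrr::map(docs, "mention")),
      seed = seed
    )
    class(bench) <- "drug_benchmark"
    bench
  })
}

#' @export
print.drug_benchmark <- function(x, ...) {
  cat("<drug_benchmark> seed ", x$seed, ": ",
      nrow(x$pairs), " labelled pairs (",
      sum(x$pairs$label == "pos"), " pos / ",
      sum(x$pairs$label == "neg"), " neg), ",
      nrow(x$documents), " documents, ",
      nrow(x$mentions), " gold mentions\n", sep = "")
  invisible(x)
}

#' Write benchmark documents and mentions as JSONL
#'
#' One JSON object per line: documents as `{doc_id, text}`, mentions /
#' annotations as `{doc_id, start, end, surface, canonical, ...}`.
#'
#' @param bench A `drug_benchmark`.
#' @param doc_path,mention_path Output paths.
#' @return `bench`, invisibly.
#' @export
write_benchmark <- function(bench, doc_path, mention_path) {
  stopifnot(inherits(bench, "drug_benchmark"))
  write_jsonl(bench$documents, doc_path)
  write_jsonl(bench$mentions, mention_path)
  invisible(bench)
}
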