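# Joint (phonetic, string) threshold tuning: evaluation metrics, the grid
# search with the simultaneous-improvement acceptance rule, and variant-
# dictionary construction at tuned thresholds.

#' Precision, recall and F1 from confusion counts
#'
#' `precision_score()` is TP / (TP + FP), `recall_score()` is
#' TP / (TP + FN), and `f1_score()` the harmonic mean of the two. Undefined
#' ratios (zero denominator) return `NA`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param precision,recall Numeric vectors of precision and recall.
#' @return Numeric vector of scores in \[0, 1\] (or `NA` where undefined).
#' @export
#' @examples
#' precision_score(417, 31)
#' recall_score(417, 25)
#' f1_score(0.931, 0.943)
precision_score <- function(tp, fp) {
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

#' @rdname precision_score
#' @export
recall_score <- function(tp, fn) {
  ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
}

#' @rdname precision_score
#' @export
f1_score <- function(precision, recall) {
  ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Evaluate a threshold pair on labelled candidate pairs
#'
#' Classifies every pair with [is_match()] and counts true positives
#' (positives accepted), false positives (negatives accepted) and false
#' negatives (positives rejected).
#'
#' @param pairs Labelled candidate pairs: every `label` must be `pos` or
#'   `neg`.
#' @param thresholds A threshold pair (see [is_match()]).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_thresholds <- function(pairs, thresholds) {
  if (!all(pairs$label %in% c("pos", "neg"))) {
    stop("all candidate pairs must be labelled pos/neg", call. = FALSE)
  }
  m <- is_match(pairs$phonetic_sim, pairs$string_sim, thresholds)
  confusion_row(tp = sum(m & pairs$label == "pos"),
                fp = sum(m & pairs$label == "neg"),
                fn = sum(!m & pairs$label == "pos"))
}

confusion_row <- function(tp, fp, fn) {
  p <- precision_score(tp, fp)
  r <- recall_score(tp, fn)
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 precision = p, recall = r, f1 = f1_score(p, r))
}

#' Default joint-threshold grid
#'
#' The Cartesian product of phonetic cutoffs 0.50 to 1.00 in steps of 0.005
#' with string cutoffs \{0\} union 0.50 to 1.00 in the same steps. String
#' cutoff 0 represents the phonetic-only rule. Grid order (phonetic varying
#' slowest) is the iteration order of [tune_thresholds()].
#'
#' @param phonetic,string Numeric vectors of cutoff values in \[0, 1\].
#' @return A tibble with columns `phonetic` and `string`, one row per pair.
#' @export
threshold_grid <- function(phonetic = seq(0.5, 1, by = 0.005),
                           string = c(0, seq(0.5, 1, by = 0.005))) {
  stopifnot(all(phonetic >= 0 & phonetic <= 1),
            all(string >= 0 & string <= 1))
  tidyr::expand_grid(phonetic = phonetic, string = string)
}

#' Tune joint similarity thresholds by grid search
#'
#' Walks the grid in order, evaluating each (phonetic, string) threshold
#' pair on the training and validation candidate sets, and replaces the
#' incumbent only when a pair strictly improves *both* F1 scores; the last
#' accepted pair wins. Grid points with undefined F1 on either set are never
#' accepted.
#'
#' @param train,valid Labelled candidate-pair tibbles (`label` in
#'   `pos`/`neg`), typically one group of drugs each.
#' @param grid A threshold grid from [threshold_grid()] (the default) or
#'   read from a TSV with columns `phonetic`, `string`.
#' @return A `threshold_fit` object: the selected `thresholds`, per-set
#'   confusion counts and metrics, and the full `grid_eval` trace (one row
#'   per grid point with both F1 scores and whether it was accepted).
#'   Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
tune_thresholds <- function(train, valid, grid = threshold_grid()) {
  stopifnot(nrow(grid) > 0, all(c("phonetic", "string") %in% names(grid)))
  for (d in list(train, valid)) {
    if (nrow(d) == 0 || !all(d$label %in% c("pos", "neg"))) {
      stop("train and valid sets must be non-empty and fully labelled",
           call. = FALSE)
    }
  }
  f1_curve <- function(pairs) {
    pos <- pairs$label == "pos"
    n_pos <- sum(pos)
    vapply(seq_len(nrow(grid)), function(i) {
      m <- pairs$phonetic_sim >= grid$phonetic[i] &
        pairs$string_sim >= grid$string[i]
      tp <- sum(m & pos)
      p <- precision_score(tp, sum(m) - tp)
      r <- recall_score(tp, n_pos - tp)
      f1_score(p, r)
    }, numeric(1))
  }
  f1_train <- f1_curve(train)
  f1_valid <- f1_curve(valid)

  best_t <- -Inf
  best_v <- -Inf
  best_i <- NA_integer_
  accepted <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (is.na(f1_train[i]) || is.na(f1_valid[i])) next
    if (f1_train[i] > best_t && f1_valid[i] > best_v) {
      best_t <- f1_train[i]
      best_v <- f1_valid[i]
      best_i <- i
      accepted[i] <- TRUE
    }
  }
  if (is.na(best_i)) {
    stop("threshold tuning failed: no grid point has defined F1 on both sets",
         call. = FALSE)
  }
  thresholds <- list(phonetic = grid$phonetic[best_i],
                     string = grid$string[best_i])
  fit <- list(
    thresholds = thresholds,
    train = evaluate_thresholds(train, thresholds),
    valid = evaluate_thresholds(valid, thresholds),
    grid_eval = tibble::tibble(
      phonetic = grid$phonetic, string = grid$string,
      f1_train = f1_train, f1_valid = f1_valid, accepted = accepted
    ),
    n_train = nrow(train), n_valid = nrow(valid)
  )
  class(fit) <- "threshold_fit"
  fit
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Joint similarity threshold fit\n")
  cat(sprintf("  thresholds: phonetic >= %.3f, string >= %.3f\n",
              x$thresholds$phonetic, x$thresholds$string))
  cat(sprintf("  train: P %.3f R %.3f F1 %.3f  (tp %d fp %d fn %d, n = %d)\n",
              x$train$precision, x$train$recall, x$train$f1,
              x$train$tp, x$train$fp, x$train$fn, x$n_train))
  cat(sprintf("  valid: P %.3f R %.3f F1 %.3f  (tp %d fp %d fn %d, n = %d)\n",
              x$valid$precision, x$valid$recall, x$valid$f1,
              x$valid$tp, x$valid$fp, x$valid$fn, x$n_valid))
  cat(sprintf("  grid: %d points, %d accepted\n",
              nrow(x$grid_eval), sum(x$grid_eval$accepted)))
  invisible(x)
}

#' @export
tidy.threshold_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$train, set = "train", .before = 1),
    dplyr::mutate(x$valid, set = "valid", .before = 1)
  )
}

#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(
    phonetic_threshold = x$thresholds$phonetic,
    string_threshold = x$thresholds$string,
    f1_train = x$train$f1, f1_valid = x$valid$f1,
    n_grid = nrow(x$grid_eval), n_accepted = sum(x$grid_eval$accepted)
  )
}

#' Split drugs into training and validation groups
#'
#' Seeded random split of a drug-name list into two groups (by default two
#' halves), used to assign candidate pairs to the tuning sets.
#'
#' @param drugs Character vector of drug names.
#' @param seed Integer seed.
#' @param prop Proportion of drugs in the training group (default 0.5).
#' @return A list with character vectors `train` and `valid`.
#' @export
split_drugs <- function(drugs, seed, prop = 0.5) {
  drugs <- unique(as.character(drugs))
  stopifnot(length(drugs) >= 2, prop > 0, prop < 1)
  withr::with_seed(seed, {
    n_train <- max(1L, round(length(drugs) * prop))
    train <- sort(sample(drugs, n_train))
    list(train = train, valid = sort(setdiff(drugs, train)))
  })
}

#' Build a variant dictionary at given thresholds
#'
#' Runs the full first-stage pipeline — blocking, the string-similarity
#' pre-filter, and the joint-threshold decision — and returns every accepted
#' (variant, canonical) entry. Each canonical drug name is also entered as a
#' variant of itself so exact mentions resolve at distance 0.
#'
#' @inheritParams generate_candidates
#' @param thresholds A threshold pair (see [is_match()]) or a
#'   `threshold_fit`.
#' @param min_string_sim Pre-filter cutoff passed to [filter_candidates()].
#' @param include_self Add identity entries for the drugs themselves
#'   (default `TRUE`).
#' @return A tibble with columns `variant`, `canonical`, `string_sim`,
#'   `phonetic_sim`.
#' @export
build_variant_dictionary <- function(drugs, vocab, thresholds,
                                     min_string_sim = 0.6,
                                     include_self = TRUE,
                                     rules = NULL) {
  drugs <- unique(pt_normalize(drugs))
  drugs <- drugs[drugs != ""]
  if (length(drugs) == 0) stop("empty drug list", call. = FALSE)
  pairs <- generate_candidates(drugs, vocab, rules = rules) |>
    filter_candidates(min_string_sim = min_string_sim) |>
    classify_candidates(thresholds) |>
    dplyr::filter(.data$match)
  dict <- tibble::tibble(
    variant = pairs$word, canonical = pairs$drug,
    string_sim = pairs$string_sim, phonetic_sim = pairs$phonetic_sim
  )
  if (include_self) {
    dict <- dplyr::bind_rows(
      tibble::tibble(variant = drugs, canonical = drugs,
                     string_sim = 1, phonetic_sim = 1),
      dict
    )
  }
  # a variant equal to a canonical name maps to itself, not to a neighbour
  dict <- dict[!(dict$variant %in% drugs & dict$canonical != dict$variant), ]
  dplyr::arrange(dict, .data$canonical, .data$variant)
}

#' Read / write threshold grids and variant dictionaries
#'
#' Grids are TSV with columns `phonetic`, `string`; variant dictionaries are
#' TSV with columns `variant`, `canonical`, `string_sim`, `phonetic_sim`.
#'
#' @param path File path.
#' @return The tibble read, or the object written (invisibly).
#' @export
read_threshold_grid <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    phonetic = readr::col_double(), string = readr::col_double()
  ))
}

#' @rdname read_threshold_grid
#' @param grid A threshold-grid tibble.
#' @export
write_threshold_grid <- function(grid, path) {
  readr::write_tsv(grid[c("phonetic", "string")], path)
  invisible(grid)
}

#' @rdname read_threshold_grid
#' @export
read_variant_dictionary <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    variant = readr::col_character(), canonical = readr::col_character(),
    string_sim = readr::col_double(), phonetic_sim = readr::col_double()
  ))
}

#' @rdname read_threshold_grid
#' @param dictionary A variant-dictionary tibble.
#' @export
write_variant_dictionary <- function(dictionary, path) {
  readr::write_tsv(
    dictionary[c("variant", "canonical", "string_sim", "phonetic_sim")], path
  )
  invisible(dictionary)
}

#' Serialize a threshold fit to JSON
#'
#' @param fit A `threshold_fit` from [tune_thresholds()].
#' @param path Output path.
#' @return `fit`, invisibly.
#' @export
write_threshold_fit <- function(fit, path) {
  stopifnot(inherits(fit, "threshold_fit"))
  jsonlite::write_json(
    list(thresholds = fit$thresholds,
         train = as.list(fit$train), valid = as.list(fit$valid)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(fit)
}
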