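test_that("precision, recall and F1 follow their defining ratios", {
  expect_equal(round(precision_score(417, 31), 3), 0.931)
  expect_equal(round(recall_score(417, 25), 3), 0.943)
  expect_equal(round(f1_score(0.931, 0.943), 3), 0.937)
  expect_equal(precision_score(0, 5), 0)
  expect_equal(recall_score(3, 0), 1)
  expect_equal(recall_score(1, 1), 0.5)
  expect_equal(f1_score(0.4, 0.4), 0.4) # harmonic-mean fixed point
  expect_true(is.na(precision_score(0, 0)))
  expect_true(is.na(recall_score(0, 0)))
  expect_true(is.na(f1_score(0, 0)))
})

toy_pairs <- function() {
  tibble::tibble(
    drug = "d", word = letters[1:3],
    phonetic_sim = c(0.9, 0.9, 0.5),
    string_sim = c(0.9, 0.9, 0.5),
    label = c("pos", "pos", "neg")
  )
}

test_that("threshold evaluation counts the three confusion cells", {
  pairs <- toy_pairs()
  r <- evaluate_thresholds(pairs, list(phonetic = 0.8, string = 0.8))
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 0L, 0L))
  r0 <- evaluate_thresholds(pairs, list(phonetic = 0, string = 0))
  expect_equal(c(r0$fp, r0$fn), c(1L, 0L))
  r1 <- evaluate_thresholds(pairs, list(phonetic = 1, string = 1))
  expect_equal(c(r1$tp, r1$fn), c(0L, 2L))
  pairs$label[1] <- "unk"
  expect_error(evaluate_thresholds(pairs, list(phonetic = 0, string = 0)),
               "labelled")
})

test_that("grid search returns a grid member that separates separable data", {
  set.seed(31)
  make_set <- function(n) tibble::tibble(
    drug = "d", word = as.character(seq_len(2 * n)),
    phonetic_sim = c(runif(n, 0.9, 1), runif(n, 0, 0.5)),
    string_sim = c(runif(n, 0.9, 1), runif(n, 0, 0.5)),
    label = rep(c("pos", "neg"), each = n)
  )
  train <- make_set(30); valid <- make_set(30)
  one <- tibble::tibble(phonetic = 0.7, string = 0.7)
  fit1 <- tune_thresholds(train, valid, grid = one)
  expect_equal(fit1$thresholds, list(phonetic = 0.7, string = 0.7))
  fit <- tune_thresholds(train, valid)
  grid <- threshold_grid()
  expect_true(any(grid$phonetic == fit$thresholds$phonetic &
                    grid$string == fit$thresholds$string))
  expect_equal(fit$train$f1, 1)
  expect_equal(fit$valid$f1, 1)
  g <- glance(fit)
  expect_equal(g$f1_train, 1)
  td <- tidy(fit)
  expect_equal(td$set, c("train", "valid"))
})

test_that("accepted grid points form a strictly improving staircase", {
  set.seed(32)
  bench <- make_benchmark(example_drugs()$drug[1:6], 10, 10, seed = 99)
  split <- split_drugs(unique(bench$pairs$drug), seed = 1)
  train <- dplyr::filter(bench$pairs, drug %in% split$train)
  valid <- dplyr::filter(bench$pairs, drug %in% split$valid)
  fit <- tune_thresholds(train, valid)
  acc <- dplyr::filter(fit$grid_eval, accepted)
  expect_gte(nrow(acc), 1)
  expect_true(all(diff(acc$f1_train) > 0))
  expect_true(all(diff(acc$f1_valid) > 0))
  sel <- dplyr::last(acc)
  expect_equal(sel$phonetic, fit$thresholds$phonetic)
  expect_equal(sel$string, fit$thresholds$string)
})

test_that("grid search lands within a step of the constrained optimum", {
  # oracle: evaluate every grid point, take max train F1 among points whose
  # validation F1 is within 0.01 of the best achievable
  bench <- make_benchmark(example_drugs()$drug, 15, 15, seed = 7)
  split <- split_drugs(unique(bench$pairs$drug), seed = 7)
  train <- dplyr::filter(bench$pairs, drug %in% split$train)
  valid <- dplyr::filter(bench$pairs, drug %in% split$valid)
  fit <- tune_thresholds(train, valid)
  ge <- fit$grid_eval
  ok <- !is.na(ge$f1_train) & !is.na(ge$f1_valid)
  best_valid <- max(ge$f1_valid[ok])
  cand <- ok & ge$f1_valid >= best_valid - 0.01
  oracle_train_f1 <- max(ge$f1_train[cand])
  expect_gte(fit$train$f1, oracle_train_f1 - 0.02)
})

test_that("raising both thresholds never grows the match set", {
  bench <- make_benchmark(example_drugs()$drug[1:5], 8, 8, seed = 13)
  pairs <- bench$pairs
  grid <- threshold_grid(phonetic = seq(0.5, 1, 0.1),
                         string = seq(0.5, 1, 0.1))
  tps <- vapply(seq_len(nrow(grid)), function(i) {
    sum(is_match(pairs$phonetic_sim, pairs$string_sim,
                 list(phonetic = grid$phonetic[i], string = grid$string[i])))
  }, numeric(1))
  for (i in seq_len(nrow(grid))) {
    dominated <- grid$phonetic >= grid$phonetic[i] &
      grid$string >= grid$string[i]
    expect_true(all(tps[dominated] <= tps[i]))
  }
})

test_that("variant dictionary entries all pass the thresholds", {
  thr <- list(phonetic = 0.8, string = 0.8)
  drugs <- c("fluoxetina", "glicose")
  dict <- build_variant_dictionary(drugs,
                                   c("fluoxetna", "glicoze", "paracetamol"),
                                   thr)
  expect_true(all(c("fluoxetna", "glicoze") %in% dict$variant))
  expect_false("paracetamol" %in% dict$variant)
  nonself <- dict[dict$variant != dict$canonical, ]
  expect_true(all(is_match(nonself$phonetic_sim, nonself$string_sim, thr)))
  # canonical names map to themselves
  self <- dict[dict$variant %in% drugs, ]
  expect_equal(self$variant, self$canonical)
  # vocab equal to the drug list gives the identity dictionary
  ident <- build_variant_dictionary(drugs, drugs, thr)
  expect_equal(ident$variant, ident$canonical)
  expect_error(build_variant_dictionary(character(), "x", thr), "empty")
})

test_that("grids, dictionaries and fits serialize and read back", {
  dir <- withr::local_tempdir()
  grid <- threshold_grid(phonetic = c(0.6, 0.7), string = c(0, 0.8))
  write_threshold_grid(grid, file.path(dir, "grid.tsv"))
  expect_equal(read_threshold_grid(file.path(dir, "grid.tsv")), grid)
  dict <- build_variant_dictionary("fluoxetina", "fluoxetna",
                                   list(phonetic = 0.8, string = 0.8))
  write_variant_dictionary(dict, file.path(dir, "dict.tsv"))
  expect_equal(read_variant_dictionary(file.path(dir, "dict.tsv")), dict)
  train <- toy_pairs(); train$label <- c("pos", "pos", "neg")
  fit <- tune_thresholds(train, train,
                         grid = tibble::tibble(phonetic = 0.8, string = 0.8))
  write_threshold_fit(fit, file.path(dir, "fit.json"))
  back <- jsonlite::fromJSON(file.path(dir, "fit.json"))
  expect_equal(back$thresholds$phonetic, 0.8)
  expect_equal(back$train$f1, fit$train$f1)
})
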