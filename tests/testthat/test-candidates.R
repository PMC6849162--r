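test_that("blocking keeps consonant-sharing or near words and drops the rest", {
  out <- generate_candidates("fluoxetina", c("fluoxetna"))
  expect_equal(nrow(out), 1)
  expect_equal(out$word, "fluoxetna")
  expect_equal(nrow(generate_candidates("fluoxetina", c("aeiou"))), 0)
  # beyond the edit-distance gate but sharing >= 3 consonantal phonemes
  out <- generate_candidates("fluoxetina", c("fluoxetinapara"))
  expect_equal(nrow(out), 1)
  expect_gt(edit_distance("fluoxetina", "fluoxetinapara"), 3)
  # the drug itself is never its own candidate
  out <- generate_candidates("fluoxetina", c("fluoxetina", "fluoxetna"))
  expect_equal(out$word, "fluoxetna")
  expect_equal(nrow(generate_candidates("fluoxetina", character())), 0)
})

test_that("blocking is a superset of the edit-distance neighbourhood", {
  set.seed(21)
  drugs <- example_drugs()$drug
  vocab <- unique(c(
    random_words(150, min_len = 4, max_len = 14),
    vapply(sample(drugs, 50, replace = TRUE),
           function(d) typo_impl_surface(d), "")
  ))
  pairs <- generate_candidates(drugs, vocab)
  for (d in sample(drugs, 5)) {
    near <- setdiff(vocab[edit_distance(rep(d, length(vocab)), vocab) <= 3], d)
    expect_true(all(near %in% pairs$word[pairs$drug == d]), info = d)
  }
  # stored similarities recompute from the stored strings
  expect_equal(pairs$string_sim, string_similarity(pairs$drug, pairs$word))
  expect_equal(pairs$phonetic_sim,
               phonetic_similarity(pairs$drug, pairs$word))
})

test_that("string-similarity pre-filter is an idempotent lower bound", {
  set.seed(22)
  pairs <- generate_candidates("fluoxetina",
                               c("fluoxetna", "fluoxe", "flux",
                                 "fluoxetinapara", "fluoxet"))
  expect_identical(filter_candidates(pairs, 0), pairs)
  once <- filter_candidates(pairs, 0.6)
  expect_true(all(once$string_sim >= 0.6))
  expect_identical(filter_candidates(once, 0.6), once)
  expect_equal(nrow(filter_candidates(pairs, 1)), 0)
})

test_that("the joint-threshold decision is inclusive and monotone", {
  expect_true(is_match(0.9, 0.84, list(phonetic = 0.844, string = 0.831)))
  expect_true(is_match(0.5, 0.5, list(phonetic = 0, string = 0)))
  expect_false(is_match(0.99, 0.99, list(phonetic = 1, string = 1)))
  expect_true(is_match(0.8, 0.8, list(phonetic = 0.8, string = 0.8)))
  set.seed(23)
  p <- runif(200); s <- runif(200)
  thr <- list(phonetic = 0.6, string = 0.55)
  base <- is_match(p, s, thr)
  for (d in c(0.05, 0.2)) {
    expect_true(all(is_match(p, s, list(phonetic = thr$phonetic + d,
                                        string = thr$string)) <= base))
    expect_true(all(is_match(p, s, list(phonetic = thr$phonetic,
                                        string = thr$string + d)) <= base))
  }
})

test_that("candidate tables round-trip through TSV", {
  pairs <- generate_candidates("fluoxetina", c("fluoxetna", "fluoxtina"))
  pairs$label <- c("pos", "neg")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(pairs, path)
  back <- read_candidates(path)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
  writeLines("drug\tword\tstring_sim\tphonetic_sim\tlabel\na\tb\t1\t1\tmaybe",
             path)
  expect_error(read_candidates(path), "label")
})
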