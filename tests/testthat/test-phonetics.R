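test_that("normalization lowercases, strips accents and keeps cedilla", {
  expect_equal(pt_normalize("Fluoxetina"), "fluoxetina")
  expect_equal(pt_normalize("INSULINA"), "insulina")
  expect_equal(pt_normalize("coração"), "coraçao")
  expect_equal(pt_normalize("dipirona 500mg!"), "dipironamg")
  expect_equal(pt_normalize("1234"), "")
  expect_error(pt_normalize("1234", strict = TRUE), "empty")
})

test_that("encoding applies the rule table deterministically", {
  expect_equal(pt_phoneme_key("hora"), pt_phoneme_key("ora"))
  expect_equal(pt_phoneme_key("cassa"), pt_phoneme_key("caça"))
  expect_equal(pt_phoneme_key("fluoxetina"), "F L U O K S E T I N A")
  expect_equal(pt_phoneme_key(""), "")
  expect_equal(nrow(pt_encode("")), 0)
  # repeated encoding of the same input is identical (pure function)
  expect_identical(pt_encode("clorpromazina"), pt_encode("clorpromazina"))
  # silent letters emit nothing, digraphs emit one symbol
  expect_equal(pt_phoneme_key("chave"), "SH A V E")
  expect_equal(pt_phoneme_key("nhoque"), "NH O K E")
})

test_that("encoded sequence is never longer than the normalized word", {
  set.seed(101)
  words <- random_words(200, alphabet = c(letters, "ç"))
  enc <- pt_encode(words)
  lens <- table(factor(enc$word, levels = unique(words)))
  # intervocalic x expands to two symbols (K S); every other rule emits at
  # most one symbol per consumed letter
  norm <- pt_normalize(unique(words))
  budget <- nchar(norm) + stringr::str_count(norm, "x")
  expect_true(all(as.integer(lens) <= budget))
  symbols <- unique(enc$symbol)
  expect_true(all(symbols %in% names(fonospell:::PT_SYMBOL_ALIAS)))
})

test_that("consonantal phonemes are the masked subsequence of the encoding", {
  expect_equal(pt_consonants("aeiou")[[1]], character(0))
  cons <- pt_consonants("fluoxetina")[[1]]
  expect_equal(cons[1:2], c("F", "L"))
  enc <- pt_encode("fluoxetina")
  expect_equal(cons, enc$symbol[enc$consonantal])
  # a word with no vowel symbols keeps its full sequence
  expect_equal(pt_consonants("brt")[[1]], c("B", "R", "T"))
})

test_that("matching consonant count is a symmetric LCS bounded by both sides", {
  expect_equal(consonant_match_count("fluoxetina", "fluoxetina"),
               length(pt_consonants("fluoxetina")[[1]]))
  expect_equal(consonant_match_count("ba", "ka"), 0L)
  expect_gte(consonant_match_count("paracetamol", "parasetamol"), 3L)
  set.seed(7)
  w1 <- random_words(40)
  w2 <- random_words(40)
  fwd <- consonant_match_count(w1, w2)
  bwd <- consonant_match_count(w2, w1)
  expect_identical(fwd, bwd)
  lens <- pmin(lengths(pt_consonants(w1)), lengths(pt_consonants(w2)))
  expect_true(all(fwd <= lens))
  # agreement with a pure-R LCS oracle on the consonant sequences
  ora <- mapply(function(a, b) lcs_oracle(pt_consonants(a)[[1]],
                                          pt_consonants(b)[[1]]),
                w1, w2)
  expect_equal(fwd, unname(as.integer(ora)))
})

test_that("multiset counting is available and at least the LCS count", {
  set.seed(11)
  w1 <- random_words(25)
  w2 <- random_words(25)
  expect_true(all(consonant_match_count(w1, w2, method = "multiset") >=
                    consonant_match_count(w1, w2)))
})

test_that("homophone-class substitutions leave the encoding unchanged", {
  cases <- rbind(
    c("hora", "ora"),
    c("cassa", "caça"), c("asse", "ace"), c("parace", "parasse"),
    c("caza", "casa"), c("mezes", "meses"),
    c("chave", "xave"), c("enchada", "enxada"),
    c("quente", "kente"), c("quilo", "kilo"),
    c("hinsulina", "insulina"), c("hglicose", "glicose")
  )
  for (i in seq_len(nrow(cases))) {
    expect_equal(pt_phoneme_key(cases[i, 1]), pt_phoneme_key(cases[i, 2]),
                 info = paste(cases[i, ], collapse = " / "))
    expect_equal(phonetic_similarity(cases[i, 1], cases[i, 2]), 1)
  }
})

test_that("a custom rule table overrides the packaged one", {
  rules <- phonetic_rules()
  rules$phonemes[rules$pattern == "ch"] <- "K"
  expect_equal(pt_phoneme_key("chave", rules = rules), "K A V E")
  expect_equal(pt_phoneme_key("chave"), "SH A V E")
})
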