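# Independent oracles used to cross-check the implementation: a pure-R
# dynamic-programming Levenshtein, a naive recursive Levenshtein for tiny
# inputs, and a pure-R longest-common-subsequence length.

lev_dp_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, rep(0L, length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

lev_recursive_oracle <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_recursive_oracle(ta, b) + 1,
      lev_recursive_oracle(a, tb) + 1,
      lev_recursive_oracle(ta, tb) + cost)
}

# Levenshtein over symbol vectors (phoneme sequences).
lcs_free_symbol_ed <- function(x, y) {
  prev <- 0:length(y)
  for (i in seq_along(x)) {
    cur <- c(i, rep(0L, length(y)))
    for (j in seq_along(y)) {
      cur[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

lcs_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  m <- matrix(0L, nx + 1, ny + 1)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      m[i + 1, j + 1] <- if (x[i] == y[j]) m[i, j] + 1L
                         else max(m[i, j + 1], m[i + 1, j])
    }
  }
  m[nx + 1, ny + 1]
}

random_words <- function(n, min_len = 3, max_len = 12,
                         alphabet = letters) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, "")
}

# Brute-force fuzzy dictionary scan used as the trie oracle.
brute_scan <- function(dictionary, query, max_ed) {
  ed <- fonospell::edit_distance(rep(query, length(dictionary)), dictionary)
  keep <- ed <= max_ed
  out <- data.frame(entry = dictionary[keep], distance = ed[keep],
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$entry), , drop = FALSE]
}

typo_impl_surface <- function(d) {
  fonospell::typo_variant(d, n_edits = sample(1:3, 1))$surface
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "fonospell")
}
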