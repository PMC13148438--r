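# Shared fixtures and small utilities for the suite.

# The running toy example: T = "abaab$" (ranks: $=1, a=2, b=3).
toy_text <- function() text_from_strings("abaab")

toy_structs <- function() build_suffix_structures(toy_text())

# Random single-sequence text over a small alphabet, deterministic under seed.
# All random helpers seed explicitly, so test order never changes fixtures.
random_text <- function(n_chars, sigma = 3L, seed = 1L) {
  stopifnot(n_chars >= 1L)
  set.seed(seed)
  text_from_strings(paste(sample(letters[seq_len(sigma)], n_chars, replace = TRUE),
                          collapse = ""))
}

random_pattern <- function(m, sigma = 3L, seed = 1L) {
  set.seed(seed)
  paste(sample(letters[seq_len(sigma)], m, replace = TRUE), collapse = "")
}

# Canonical key for a set of (p_start, t_start, length) triples.
triple_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$p_start, df$t_start, df$length, sep = ":"))
}

expect_same_triples <- function(got, want) {
  expect_identical(triple_key(got), triple_key(want))
}

# Naive lexicographic suffix sort on integer ranks (independent oracle for SA).
naive_suffix_array <- function(sym) {
  n <- length(sym)
  suff <- vapply(seq_len(n),
                 function(i) paste(sprintf("%03d", sym[i:n]), collapse = ","),
                 character(1))
  order(suff, method = "radix")
}

# Direct character-comparison lcp of two suffixes of sym.
naive_lcp_pair <- function(sym, i, j) {
  n <- length(sym)
  h <- 0L
  while (i + h <= n && j + h <= n && sym[i + h] == sym[j + h]) h <- h + 1L
  h
}
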