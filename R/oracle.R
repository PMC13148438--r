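#' Brute-force enumeration of long locally maximal exact matches
#'
#' Ground truth for the index-based query. A locally maximal exact match (LEM)
#' `P[i, j] = T[i', j']` cannot be *simultaneously* extended in the pattern and
#' the text on either side: `(i = 1 or i' = 1 or P[i-1] != T[i'-1])` and
#' `(j = m or j' = n or P[j+1] != T[j'+1])`. On a fixed diagonal
#' (`i' - i` constant) these are exactly the maximal runs of agreeing symbols,
#' so the enumerator scans every diagonal and reports maximal runs of length at
#' least `L`.
#'
#' @param text a `lem_text`.
#' @param pattern integer ranks or a pattern string.
#' @param L minimum reported length (`>= 1`).
#' @return data.frame with columns `p_start`, `t_start`, `length`, sorted.
#' @export
enumerate_lems_bruteforce <- function(text, pattern, L) {
  if (is.character(pattern)) pattern <- map_pattern(text, pattern)
  pat <- as.integer(pattern)
  m <- length(pat)
  sym <- text$symbols
  n <- length(sym)
  stopifnot(L >= 1L)
  ps <- integer(0); ts <- integer(0); ln <- integer(0)
  if (m > 0L) {
    for (delta in (1L - m):(n - 1L)) {
      is <- max(1L, 1L - delta); ie <- min(m, n - delta)
      if (ie - is + 1L < L) next
      eq <- pat[is:ie] == sym[(is + delta):(ie + delta)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      keep <- r$values & r$lengths >= L
      if (any(keep)) {
        st <- ends[keep] - r$lengths[keep] + 1L
        ps <- c(ps, is + st - 1L)
        ts <- c(ts, is + st - 1L + delta)
        ln <- c(ln, r$lengths[keep])
      }
    }
  }
  out <- data.frame(p_start = ps, t_start = ts, length = ln)
  out[order(out$p_start, out$t_start, out$length), , drop = FALSE]
}

#' Brute-force enumeration of maximal exact matches
#'
#' A maximal exact match (MEM) cannot be extended in the pattern: for each
#' pattern position the longest match starting there (the matching statistic)
#' is right-maximal by definition, and it is left-maximal unless the position
#' before extends one further. Every text occurrence of each maximal substring
#' is reported, so the MEM triples are a subset of the LEM triples.
#'
#' @param text a `lem_text`.
#' @param pattern integer ranks or a string.
#' @param structs optional precomputed `suffix_structures` for `text`.
#' @return data.frame with columns `p_start`, `t_start`, `length`, sorted.
#' @export
enumerate_mems_bruteforce <- function(text, pattern, structs = NULL) {
  if (is.null(structs)) structs <- build_suffix_structures(text)
  if (is.character(pattern)) pattern <- map_pattern(text, pattern)
  pat <- as.integer(pattern)
  m <- length(pat)
  ms <- compute_ms_oracle(structs, pat)
  ps <- integer(0); ts <- integer(0); ln <- integer(0)
  for (i in seq_len(m)) {
    if (ms$len[i] == 0L) next
    if (i > 1L && ms$len[i - 1L] == ms$len[i] + 1L) next  # left-extendable
    # all occurrences: the SA rows sharing a >= len prefix with the witness
    lo <- ms$row[i]
    hi <- lo
    while (hi < structs$text$n && structs$LCP[hi + 1L] >= ms$len[i]) hi <- hi + 1L
    occ <- structs$SA[lo:hi]
    ps <- c(ps, rep(i, length(occ)))
    ts <- c(ts, occ)
    ln <- c(ln, rep(ms$len[i], length(occ)))
  }
  out <- data.frame(p_start = ps, t_start = ts, length = ln)
  out[order(out$p_start, out$t_start, out$length), , drop = FALSE]
}

#' Simulate a haplotype panel and a held-out query haplotype
#'
#' Emulates the repetitive texts the index is designed for: a founder sequence
#' is copied `n_haplotypes` times, each copy independently point-mutated at
#' `mutation_rate` per site (a mutated site is replaced by a uniformly chosen
#' *different* symbol), and the copies are concatenated with per-sequence
#' sentinels. One extra mutated copy is returned, sentinel-free, as the query
#' pattern. Deterministic for a fixed `seed`.
#'
#' @param n_haplotypes number of haplotypes in the panel.
#' @param haplotype_length founder length (sites).
#' @param mutation_rate per-site mutation probability in `[0, 1]`.
#' @param alphabet symbols to draw from (default 4-letter nucleotides).
#' @param seed RNG seed (applied via `set.seed`).
#' @return list with `text` (a `lem_text`), `pattern` (string), `haplotypes`
#'   (character vector) and `founder`.
#' @export
simulate_panel <- function(n_haplotypes, haplotype_length,
                           mutation_rate = 0.01,
                           alphabet = c("a", "c", "g", "t"),
                           seed = NULL) {
  stopifnot(n_haplotypes >= 1L, haplotype_length >= 1L,
            mutation_rate >= 0, mutation_rate <= 1, length(alphabet) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  founder <- sample(alphabet, haplotype_length, replace = TRUE)
  mutate <- function(h) {
    hit <- stats::runif(length(h)) < mutation_rate
    if (any(hit)) {
      k <- sum(hit)
      shift <- sample.int(length(alphabet) - 1L, k, replace = TRUE)
      h[hit] <- alphabet[((match(h[hit], alphabet) - 1L + shift) %% length(alphabet)) + 1L]
    }
    h
  }
  haps <- vapply(seq_len(n_haplotypes),
                 function(i) paste(mutate(founder), collapse = ""), character(1))
  pattern <- paste(mutate(founder), collapse = "")
  list(text = text_from_strings(haps, names = paste0("hap", seq_len(n_haplotypes))),
       pattern = pattern, haplotypes = haps,
       founder = paste(founder, collapse = ""))
}
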