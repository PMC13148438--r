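#' Suffix array by prefix doubling
#'
#' Reference O(n log n) construction used for index building at desk scale and
#' as the testing oracle. Works on the dense integer ranks of a `lem_text`, so
#' it is locale-free.
#'
#' @param text a `lem_text` (must end in a sentinel; see [validate_text()]).
#' @return integer vector `SA` of length n: `SA[i]` is the start of the i-th
#'   lexicographically smallest suffix.
#' @export
build_suffix_array <- function(text) {
  validate_text(text)
  sym <- text$symbols
  n <- length(sym)
  if (n == 1L) return(1L)
  rk <- sym
  k <- 1L
  repeat {
    rk2 <- if (k < n) c(rk[(k + 1L):n], rep(0L, k)) else rep(0L, n)
    o <- order(rk, rk2, method = "radix")
    r1 <- rk[o]; r2 <- rk2[o]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    new <- cumsum(changed)
    rk[o] <- as.integer(new)
    if (new[n] == n) break
    k <- k * 2L
    if (k >= n) { # ranks all distinct next round at the latest
      rk2 <- if (k < n) c(rk[(k + 1L):n], rep(0L, k)) else rep(0L, n)
      o <- order(rk, rk2, method = "radix")
      rk[o] <- seq_len(n)
      break
    }
  }
  order(rk, method = "radix")
}

#' Inverse suffix array
#' @param sa suffix array.
#' @return integer vector with `ISA[SA[i]] = i`.
#' @export
build_isa <- function(sa) {
  isa <- integer(length(sa))
  isa[sa] <- seq_along(sa)
  isa
}

#' Burrows-Wheeler transform from a suffix array
#'
#' `BWT[i]` is the symbol preceding the i-th smallest suffix, wrapping to the
#' last symbol of the text when `SA[i] = 1`.
#' @param text a `lem_text`.
#' @param sa its suffix array.
#' @return integer vector of symbol ranks, length n.
#' @export
build_bwt <- function(text, sa) {
  sym <- text$symbols
  j <- sa - 1L
  j[j == 0L] <- length(sym)
  sym[j]
}

#' LCP array via the PLCP identity
#'
#' Computes the permuted LCP array in text order by Kasai's amortized scan and
#' places it in suffix-array order (`LCP[i] = PLCP[SA[i]]`, `LCP[1] = 0`).
#' @param text a `lem_text`.
#' @param sa suffix array.
#' @param isa inverse suffix array.
#' @return integer LCP array of length n.
#' @export
build_lcp <- function(text, sa, isa) {
  sym <- text$symbols
  n <- length(sym)
  plcp <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    r <- isa[i]
    if (r > 1L) {
      j <- sa[r - 1L]
      while (i + h <= n && j + h <= n && sym[i + h] == sym[j + h]) h <- h + 1L
      plcp[i] <- h
      if (h > 0L) h <- h - 1L
    } else {
      plcp[i] <- 0L
      h <- 0L
    }
  }
  plcp[sa]
}

#' LF mapping and the phi / phi-inverse permutations
#'
#' `LF[i]` is the suffix-array row of the suffix one text position earlier than
#' row i (wrapping from suffix 1 to suffix n). `phi[j]` is the suffix
#' immediately above suffix `j` in suffix-array order (`phi[SA[k]] = SA[k-1]`,
#' with `phi[SA[1]] = SA[n]`), and `phi_inv` is its inverse.
#' @param text a `lem_text`.
#' @param sa suffix array.
#' @param isa inverse suffix array.
#' @return list with integer vectors `LF`, `phi`, `phi_inv`.
#' @export
build_lf_phi <- function(text, sa, isa) {
  n <- length(sa)
  prev <- sa - 1L
  prev[prev == 0L] <- n
  lf <- isa[prev]
  phi <- integer(n)
  phi[sa] <- c(sa[n], sa[-n])
  phi_inv <- integer(n)
  phi_inv[phi] <- seq_len(n)
  list(LF = lf, phi = phi, phi_inv = phi_inv)
}

#' Run-length encode a BWT
#'
#' @param bwt integer symbol vector.
#' @return list of class `rlbwt` with `char` (run symbols), `start` (1-based run
#'   starts `l_i`), and `r` (run count).
#' @export
run_length_encode <- function(bwt) {
  if (length(bwt) == 0L) stop("empty BWT")
  change <- c(TRUE, bwt[-1L] != bwt[-length(bwt)])
  start <- which(change)
  structure(list(char = bwt[start], start = start, r = length(start)),
            class = "rlbwt")
}

#' Build the full bundle of uncompressed suffix structures
#'
#' Oracle bundle: SA, ISA, BWT, LCP, PLCP, LF, phi, phi_inv and the RLBWT for a
#' text. Used for desk-scale index construction and as ground truth in tests.
#' @param text a `lem_text`.
#' @return list of class `suffix_structures` (also carries `text`).
#' @export
build_suffix_structures <- function(text) {
  sa <- build_suffix_array(text)
  isa <- build_isa(sa)
  bwt <- build_bwt(text, sa)
  lcp <- build_lcp(text, sa, isa)
  plcp <- integer(length(sa))
  plcp[sa] <- lcp
  maps <- build_lf_phi(text, sa, isa)
  structure(
    list(text = text, SA = sa, ISA = isa, BWT = bwt, LCP = lcp, PLCP = plcp,
         LF = maps$LF, phi = maps$phi, phi_inv = maps$phi_inv,
         rlbwt = run_length_encode(bwt)),
    class = "suffix_structures")
}

#' Invert a BWT by an LF walk
#'
#' Reconstructs the text from the BWT alone: LF is derived by stable counting
#' (the j-th occurrence of a symbol in the BWT is the j-th occurrence in the
#' first column), and the walk starts at the row holding the text's first
#' suffix — the unique row whose BWT symbol is the final sentinel `T[n]`.
#' @param bwt integer symbol vector (ranks).
#' @param sentinel_count number of sentinel ranks; the final sentinel has rank
#'   `sentinel_count`.
#' @return integer symbol vector equal to the original text.
#' @export
invert_bwt <- function(bwt, sentinel_count) {
  n <- length(bwt)
  lf <- integer(n)
  lf[order(bwt, method = "radix")] <- seq_len(n)   # radix order is stable
  row <- which(bwt == sentinel_count)              # row of suffix 1
  if (length(row) != 1L) stop("final sentinel must occur exactly once in the BWT")
  out <- integer(n)
  for (i in seq(n, 1L)) {
    out[i] <- bwt[row]
    row <- lf[row]
  }
  out
}
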