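# Diagonal machinery shared by the matching-statistics oracle and the
# brute-force LEM enumerator: for one diagonal (fixed text_start - pat_start
# offset), `diag_remaining` gives at each aligned pattern position the length
# of the maximal match continuing from there.
diag_remaining <- function(eq) {
  ld <- length(eq)
  f <- which(!eq)
  if (length(f) == 0L) return(ld - seq_len(ld) + 1L)
  f_pad <- c(f, ld + 1L)
  f_pad[findInterval(seq_len(ld) - 1L, f) + 1L] - seq_len(ld)
}

#' Matching statistics of a pattern (oracle computation)
#'
#' For each pattern position `i`, the length of the longest substring of `P`
#' starting at `i` that occurs in the text, together with a witness occurrence:
#' the SA value (`suff`) and row (`row`) of the smallest suffix-array row among
#' the maximizers. Computed from the full uncompressed structures by a diagonal
#' sweep (every pattern-vs-text alignment is examined), so it is independent of
#' the compressed index and serves as ground truth; positions whose best match
#' has length 0 carry `NA` witnesses.
#'
#' @param structs a `suffix_structures` bundle.
#' @param pattern integer symbol ranks (see [map_pattern()]) or a string.
#' @return object of class `ms_table`: list of integer vectors `len`, `suff`,
#'   `row` (and `i`, `w`, `x` once augmented), plus `m`.
#' @export
compute_ms_oracle <- function(structs, pattern) {
  if (is.character(pattern)) pattern <- map_pattern(structs$text, pattern)
  pat <- as.integer(pattern)
  m <- length(pat)
  sym <- structs$text$symbols
  n <- length(sym)
  len <- integer(m); wit <- integer(m)
  if (m > 0L) {
    for (delta in (1L - m):(n - 1L)) {
      is <- max(1L, 1L - delta); ie <- min(m, n - delta)
      if (ie < is) next
      ii <- is:ie
      rem <- diag_remaining(pat[ii] == sym[ii + delta])
      upd <- rem > len[ii]
      if (any(upd)) {
        len[ii[upd]] <- rem[upd]
        wit[ii[upd]] <- ii[upd] + delta
      }
    }
  }
  suff <- rep(NA_integer_, m); row <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (len[i] == 0L) next
    r0 <- structs$ISA[wit[i]]
    while (r0 > 1L && structs$LCP[r0] >= len[i]) r0 <- r0 - 1L
    row[i] <- r0
    suff[i] <- structs$SA[r0]
  }
  structure(list(len = len, suff = suff, row = row, m = m), class = "ms_table")
}

#' @export
print.ms_table <- function(x, ...) {
  cat(sprintf("matching statistics for a pattern of length %d\n", x$m))
  print(utils::head(data.frame(pos = seq_len(x$m), len = x$len, suff = x$suff,
                               row = x$row), 10L))
  if (x$m > 10L) cat("...\n")
  invisible(x)
}

#' Augment matching statistics with move-structure interval indices
#'
#' Fills, for each entry, the LF input interval containing `row` (`i`), and the
#' phi / phi-inverse input intervals containing `suff` (`w`, `x`). Binary
#' search over interval starts is permitted here: augmentation is
#' preprocessing, not part of the per-step query path. Length-0 entries keep
#' `NA` indices and are never consumed by the query.
#'
#' @param idx an `optbwtrl` of the same text.
#' @param ms an `ms_table` from [compute_ms_oracle()].
#' @return the augmented `ms_table`.
#' @export
augment_ms <- function(idx, ms) {
  ok <- !is.na(ms$row)
  ms$i <- ms$w <- ms$x <- rep(NA_integer_, ms$m)
  ms$i[ok] <- interval_of(idx$mv_lf, ms$row[ok])
  ms$w[ok] <- interval_of(idx$mv_phi, ms$suff[ok])
  ms$x[ok] <- interval_of(idx$mv_phiinv, ms$suff[ok])
  ms
}

#' Balanced interval of one length-L pattern window
#'
#' Computes the balanced sa_lcp-interval of `P[f, f+L-1]` by `L` backward
#' extension steps starting from the interval of the empty string (the full
#' suffix-array range), using only the compressed index. Returns `NULL` when
#' the window does not occur in the text (including windows containing symbols
#' absent from the text).
#'
#' @param idx an `optbwtrl`.
#' @param pattern integer ranks or string.
#' @param f window start (`1 <= f <= m - L + 1`).
#' @param L window length (threshold).
#' @param variant extension variant, `"rank_select"` or `"run_scan"`.
#' @param ctr optional work counter.
#' @return a `sa_lcp_interval` (13-tuple) or `NULL`.
#' @export
seed_window <- function(idx, pattern, f, L,
                        variant = c("rank_select", "run_scan"), ctr = NULL) {
  variant <- match.arg(variant)
  pat <- if (is.character(pattern)) stop("seed_window expects mapped ranks") else
    as.integer(pattern)
  m <- length(pat)
  if (L > m) return(NULL)
  stopifnot(f >= 1L, f <= m - L + 1L)
  itv <- root_interval(idx)
  for (pos in seq(f + L - 1L, f)) {
    itv <- extend_interval(idx, itv, pat[pos], variant = variant, ctr = ctr)
    if (is.null(itv)) return(NULL)
  }
  itv
}
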