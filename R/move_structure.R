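#' Disjoint interval sequences
#'
#' A disjoint interval sequence represents a bijection f on `[1, n]` that is
#' piecewise a shift: input intervals `[p_i, p_{i+1}-1]` partition `[1, n]`
#' (with `p_{k+1} = n+1`), each mapped rigidly onto the output interval starting
#' at `q_i`, and the output intervals also partition `[1, n]`.
#'
#' @param p integer vector of input-interval starts (strictly increasing,
#'   `p[1] = 1`).
#' @param q integer vector of output-interval starts (`q_i = f(p_i)`).
#' @param n domain size.
#' @return object of class `dis` with fields `p`, `q`, `k`, `n`.
#' @export
dis_new <- function(p, q, n) {
  p <- as.integer(p); q <- as.integer(q); n <- as.integer(n)
  seqi <- structure(list(p = p, q = q, k = length(p), n = n), class = "dis")
  validate_dis(seqi)
}

#' Validate the three disjoint-interval-sequence conditions
#'
#' (i) `p_1 = 1 < p_2 < ... < p_k <= n`; (ii) and (iii) the output intervals,
#' taken in sorted order, tile `[1, n]` exactly.
#' @param seq a `dis`.
#' @return `seq` invisibly; errors on violation.
#' @export
validate_dis <- function(seq) {
  p <- seq$p; q <- seq$q; n <- seq$n; k <- seq$k
  if (k < 1L || p[1L] != 1L || any(diff(p) <= 0L) || p[k] > n)
    stop("input interval starts must satisfy p_1 = 1 < p_2 < ... < p_k <= n")
  len <- diff(c(p, n + 1L))
  if (length(q) != k || any(q < 1L) || any(q + len - 1L > n))
    stop("output intervals out of range")
  o <- order(q)
  if (!(q[o[1L]] == 1L && all(q[o][-1L] == (q[o] + len[o])[-k])))
    stop("output intervals do not tile [1, n]")
  invisible(seq)
}

#' Minimal disjoint interval sequence of a permutation
#'
#' The input intervals are the conserved intervals of the permutation: a new
#' interval starts at 1 and wherever `perm(i) - i` changes.
#' @param perm a permutation of `[1, n]` as an integer vector.
#' @return a `dis` representing `perm`.
#' @export
from_permutation <- function(perm) {
  perm <- as.integer(perm)
  n <- length(perm)
  if (n < 1L || anyNA(perm) || !identical(sort(perm), seq_len(n)))
    stop("`perm` must be a bijection on [1, n]")
  off <- perm - seq_len(n)
  starts <- c(1L, which(off[-1L] != off[-n]) + 1L)
  dis_new(starts, perm[starts], n)
}

#' Evaluate the bijection represented by a sequence at every position
#' @param seq a `dis`.
#' @return integer vector `f` of length n with `f[i]` the image of `i`.
#' @export
eval_dis <- function(seq) {
  len <- diff(c(seq$p, seq$n + 1L))
  seq_len(seq$n) + rep(seq$q - seq$p, times = len)
}

#' Balance a disjoint interval sequence
#'
#' Splits input intervals until every output interval overlaps at most `2d - 1`
#' input intervals, so a move query resolves the destination interval by a
#' bounded forward scan. Splitting rule: while some output interval overlaps at
#' least `2d` input intervals, split its pair at the position aligned with the
#' d-th overlapped input-interval boundary; the result has at most
#' `k + ceiling(k/(d-1))` intervals (`2k` for the default `d = 2`) and
#' represents the same bijection.
#' @param seq a `dis`.
#' @param d balancing parameter, integer `>= 2`.
#' @return a balanced `dis` (returned unchanged if already balanced).
#' @export
balance <- function(seq, d = 2L) {
  d <- as.integer(d)
  if (is.na(d) || d < 2L) stop("balancing parameter d must be an integer >= 2")
  p <- seq$p; q <- seq$q; n <- seq$n
  guard <- 4L * length(p) + 16L
  repeat {
    k <- length(p)
    len <- diff(c(p, n + 1L))
    inside <- findInterval(q + len - 1L, p) - findInterval(q, p)
    j <- which(inside >= 2L * d - 1L)        # overlaps = inside + 1 >= 2d
    if (length(j) == 0L) break
    j <- j[1L]
    t0 <- findInterval(q[j], p)   # first overlapped input interval
    s <- p[t0 + d]                # d-th input start inside: part 1 overlaps d
    t <- p[j] + (s - q[j])        # aligned split point, p[j] < t < p[j+1]
    p <- append(p, t, after = j)
    q <- append(q, s, after = j)
    if ((guard <- guard - 1L) < 0L) stop("balancing did not converge")
  }
  structure(list(p = as.integer(p), q = as.integer(q), k = length(p), n = n),
            class = "dis")
}

#' Build a move data structure
#'
#' Balances the sequence, precomputes for every interval the index of the input
#' interval containing its output start (`succ_ptr`), and optionally attaches
#' one PLCP sample per input interval:
#' * role `"plcp_at_start"` (for a phi sequence): sample `LCP+[x] = PLCP[p_x]`,
#'   so `PLCP[i] = LCP+[x] - (i - p_x)` throughout the interval;
#' * role `"plcp_of_phi_inv_at_start"` (for a phi-inverse sequence): sample
#'   `LCP-[x] = PLCP[f(p_x)]`, so `PLCP[f(i)] = LCP-[x] - (i - p_x)`.
#'
#' @param seq a `dis` (will be balanced internally).
#' @param d balancing parameter.
#' @param plcp full oracle PLCP array (construction-time only), required when
#'   `sample_role != "none"`.
#' @param sample_role one of `"none"`, `"plcp_at_start"`,
#'   `"plcp_of_phi_inv_at_start"`.
#' @return object of class `move_structure` with fields `p`, `q`, `k`, `n`,
#'   `d`, `succ`, `samp`, `role`.
#' @export
build_move_structure <- function(seq, d = 2L,
                                 plcp = NULL,
                                 sample_role = c("none", "plcp_at_start",
                                                 "plcp_of_phi_inv_at_start")) {
  sample_role <- match.arg(sample_role)
  bal <- balance(seq, d)
  succ <- findInterval(bal$q, bal$p)
  samp <- NULL
  if (sample_role != "none") {
    if (is.null(plcp)) stop("PLCP array required for sampled roles")
    samp <- switch(sample_role,
                   plcp_at_start = plcp[bal$p],
                   plcp_of_phi_inv_at_start = plcp[bal$q])
  }
  structure(list(p = bal$p, q = bal$q, k = bal$k, n = bal$n, d = d,
                 succ = as.integer(succ), samp = samp, role = sample_role),
            class = "move_structure")
}

#' Move query
#'
#' Maps position `i` (lying in input interval `x`) to its image `i'` under the
#' represented bijection and the index `x'` of the input interval containing
#' `i'`. `x'` is found by a bounded forward scan from the precomputed successor
#' pointer; callers must carry `x` correctly — an inconsistent `x` is a
#' contract violation, not a recoverable condition.
#' @param ms a `move_structure`.
#' @param i position in `[1, n]`.
#' @param x index of the input interval containing `i`.
#' @return integer vector `c(i_prime, x_prime)`.
#' @export
move_query <- function(ms, i, x) {
  p <- ms$p
  k <- ms$k
  if (is.na(x) || x < 1L || x > k || i < p[x] ||
      (if (x < k) i >= p[x + 1L] else i > ms$n))
    stop("move_query: position ", i, " not in input interval ", x,
         " (caller must maintain the interval index)")
  i2 <- ms$q[x] + (i - p[x])
  x2 <- ms$succ[x]
  while (x2 < k && i2 >= p[x2 + 1L]) x2 <- x2 + 1L
  c(i2, x2)
}

#' PLCP query on a phi move structure
#'
#' For a structure with role `"plcp_at_start"` built from a phi interval
#' sequence, returns `PLCP[i]` in constant time given the containing interval.
#' @inheritParams move_query
#' @return `PLCP[i]`.
#' @export
plcp_query <- function(ms, i, x) {
  if (!identical(ms$role, "plcp_at_start"))
    stop("plcp_query requires a move structure with role 'plcp_at_start'")
  p <- ms$p
  if (is.na(x) || x < 1L || x > ms$k || i < p[x] ||
      (if (x < ms$k) i >= p[x + 1L] else i > ms$n))
    stop("plcp_query: position ", i, " not in input interval ", x)
  ms$samp[x] - (i - p[x])
}

#' PLCP-of-phi-inverse query on a phi-inverse move structure
#'
#' For a structure with role `"plcp_of_phi_inv_at_start"` built from a
#' phi-inverse interval sequence, returns `PLCP[phi_inv(i)]` — the LCP value
#' just below suffix `i`'s row — in constant time.
#' @inheritParams move_query
#' @return `PLCP[phi_inv(i)]`.
#' @export
plcp_of_phi_inv_query <- function(ms, i, x) {
  if (!identical(ms$role, "plcp_of_phi_inv_at_start"))
    stop("plcp_of_phi_inv_query requires role 'plcp_of_phi_inv_at_start'")
  p <- ms$p
  if (is.na(x) || x < 1L || x > ms$k || i < p[x] ||
      (if (x < ms$k) i >= p[x + 1L] else i > ms$n))
    stop("plcp_of_phi_inv_query: position ", i, " not in input interval ", x)
  ms$samp[x] - (i - p[x])
}

#' Locate the input interval containing a position
#'
#' Binary search over interval starts. Construction and testing helper only:
#' query algorithms carry interval indices and never call this on the hot path.
#' @param ms a `move_structure` (or `dis`).
#' @param i positions.
#' @return interval indices.
#' @export
interval_of <- function(ms, i) findInterval(i, ms$p)
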