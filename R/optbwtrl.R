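#' Build the run-length compressed index
#'
#' Assembles the full query index from a text. Construction uses the
#' uncompressed suffix structures and then discards them: the index retains
#' only per-interval data (move structures, samples, jump arrays), never a
#' plain suffix array, so its size scales with the number of balanced
#' intervals rather than with the text length.
#'
#' Components:
#' * `mv_lf`: move structure for LF; every input interval lies within one BWT
#'   run.
#' * `mv_phi`: move structure for phi over the run-top suffix starts
#'   `p+ = sort(SA[l_1..l_r])`, carrying `PLCP[p]` samples (`LCP+`), so
#'   `phi(i)` and `PLCP[i]` come from one query.
#' * `mv_phiinv`: move structure for phi-inverse over the run-bottom suffix
#'   starts, carrying `PLCP[phi_inv(p)]` samples (`LCP-`).
#' * `Lfirst`, occurrence lists (`rank_select_next()`), and the run-jump
#'   arrays `ND`/`PD` over the LF input intervals.
#' * Suffix-array samples at LF-interval starts/ends (`SAplus`, `SAminus`) and
#'   their interval indices in the phi and phi-inverse structures
#'   (`SAphi_plus`, `SAphi_minus`, `SAindex_plus`, `SAindex_minus`).
#'
#' @param text a `lem_text`.
#' @param d balancing parameter (default 2: at most `2k` intervals per
#'   structure).
#' @return object of class `optbwtrl`.
#' @export
build_index <- function(text, d = 2L) {
  st <- build_suffix_structures(text)
  n <- text$n
  r <- st$rlbwt$r
  run_start <- st$rlbwt$start

  # LF sequence: one pair per BWT run (LF is a shift within each run).
  seq_lf <- dis_new(run_start, st$LF[run_start], n)
  stopifnot(identical(eval_dis(seq_lf), st$LF))
  mv_lf <- build_move_structure(seq_lf, d = d)

  # phi over run-top suffix values; phi-inverse over run-bottom suffix values.
  p_plus <- sort(st$SA[run_start])
  seq_phi <- dis_new(p_plus, st$phi[p_plus], n)
  stopifnot(identical(eval_dis(seq_phi), st$phi))
  mv_phi <- build_move_structure(seq_phi, d = d, plcp = st$PLCP,
                                 sample_role = "plcp_at_start")

  run_bottom <- if (r > 1L) c(run_start[-1L] - 1L, n) else n
  p_minus <- sort(st$SA[run_bottom])
  seq_phiinv <- dis_new(p_minus, st$phi_inv[p_minus], n)
  stopifnot(identical(eval_dis(seq_phiinv), st$phi_inv))
  mv_phiinv <- build_move_structure(seq_phiinv, d = d, plcp = st$PLCP,
                                    sample_role = "plcp_of_phi_inv_at_start")

  k <- mv_lf$k
  p_lf <- mv_lf$p
  Lfirst <- st$BWT[p_lf]
  # run-change jumps over the balanced LF intervals
  change <- c(TRUE, Lfirst[-1L] != Lfirst[-k])
  run_id <- cumsum(change)
  first_of_run <- which(change)
  last_of_run <- c(first_of_run[-1L] - 1L, k)
  ND <- c(first_of_run[-1L], k + 1L)[run_id]
  PD <- c(-1L, last_of_run[-length(last_of_run)])[run_id]

  SAplus <- st$SA[p_lf]
  SAminus <- st$SA[c(p_lf[-1L] - 1L, n)]
  SAphi_plus <- interval_of(mv_phi, SAplus)
  SAphi_minus <- interval_of(mv_phi, SAminus)
  SAindex_plus <- interval_of(mv_phiinv, SAplus)
  SAindex_minus <- interval_of(mv_phiinv, SAminus)

  sigma <- text$sentinel_count + length(text$alphabet)
  occ <- lapply(seq_len(sigma), function(cc) which(Lfirst == cc))

  idx <- structure(
    list(mv_lf = mv_lf, mv_phi = mv_phi, mv_phiinv = mv_phiinv,
         Lfirst = Lfirst, occ = occ, ND = as.integer(ND), PD = as.integer(PD),
         SAplus = SAplus, SAminus = SAminus,
         SAphi_plus = SAphi_plus, SAphi_minus = SAphi_minus,
         SAindex_plus = SAindex_plus, SAindex_minus = SAindex_minus,
         n = n, r = r, d = as.integer(d),
         alphabet = text$alphabet, sentinel_count = text$sentinel_count,
         seq_names = text$names, seq_ends = text$seq_ends),
    class = "optbwtrl")
  idx
}

#' @export
print.optbwtrl <- function(x, ...) {
  cat(sprintf(paste0("optbwtrl index: n = %d, r = %d runs, d = %d\n",
                     "  intervals: LF %d, phi %d, phi-inverse %d\n",
                     "  stored elements: %d\n"),
              x$n, x$r, x$d, x$mv_lf$k, x$mv_phi$k, x$mv_phiinv$k,
              index_element_count(x)))
  invisible(x)
}

#' Count the stored integer/symbol elements of an index
#'
#' Space-honesty accounting: everything the index stores, excluding the O(1)
#' scalars and the O(#sequences) name table. Scales with the balanced interval
#' counts, never with the text length.
#' @param idx an `optbwtrl`.
#' @return element count.
#' @export
index_element_count <- function(idx) {
  mv_elems <- function(ms) length(ms$p) + length(ms$q) + length(ms$succ) +
    length(ms$samp)
  mv_elems(idx$mv_lf) + mv_elems(idx$mv_phi) + mv_elems(idx$mv_phiinv) +
    length(idx$Lfirst) + sum(lengths(idx$occ)) + length(idx$ND) +
    length(idx$PD) + length(idx$SAplus) + length(idx$SAminus) +
    length(idx$SAphi_plus) + length(idx$SAphi_minus) +
    length(idx$SAindex_plus) + length(idx$SAindex_minus)
}

#' One LF step
#'
#' Maps suffix-array row `i` (in LF input interval `x`) to `LF[i]` and the
#' interval containing it.
#' @param idx an `optbwtrl`.
#' @param i row.
#' @param x LF input interval of `i`.
#' @param ctr optional work counter environment (field `lf`).
#' @return `c(row, interval)`.
#' @export
lf_step <- function(idx, i, x, ctr = NULL) {
  if (!is.null(ctr)) ctr$lf <- ctr$lf + 1L
  move_query(idx$mv_lf, i, x)
}

#' One phi step with its PLCP value
#'
#' Given suffix `s` in phi input interval `w`, returns the suffix directly
#' above it in suffix-array order, `PLCP[s]` (the LCP between `s` and that
#' suffix), and the interval of the result.
#' @param idx an `optbwtrl`.
#' @param s text position (suffix).
#' @param w phi input interval of `s`.
#' @param ctr optional work counter environment (field `phi`).
#' @return `c(phi_s, plcp_s, interval)`.
#' @export
phi_step <- function(idx, s, w, ctr = NULL) {
  if (!is.null(ctr)) ctr$phi <- ctr$phi + 1L
  ms <- idx$mv_phi
  pl <- plcp_query(ms, s, w)
  mv <- move_query(ms, s, w)
  c(mv[1L], pl, mv[2L])
}

#' One phi-inverse step with the LCP below
#'
#' Given suffix `s` in phi-inverse input interval `x`, returns the suffix
#' directly below it in suffix-array order, `PLCP[phi_inv(s)]` (the LCP
#' between `s`'s row and the row below), and the interval of the result.
#' @param idx an `optbwtrl`.
#' @param s text position (suffix).
#' @param x phi-inverse input interval of `s`.
#' @param ctr optional work counter environment (field `phiinv`).
#' @return `c(phi_inv_s, plcp_below, interval)`.
#' @export
phi_inv_step <- function(idx, s, x, ctr = NULL) {
  if (!is.null(ctr)) ctr$phiinv <- ctr$phiinv + 1L
  ms <- idx$mv_phiinv
  pl <- plcp_of_phi_inv_query(ms, s, x)
  mv <- move_query(ms, s, x)
  c(mv[1L], pl, mv[2L])
}

#' Nearest LF interval with a given BWT symbol
#'
#' Rank-select over `Lfirst` as per-symbol sorted occurrence lists: the first
#' (direction `"down"`) or last (direction `"up"`) interval index in
#' `[from, to]` whose BWT symbol is `c`, or `NA` if absent.
#' @param idx an `optbwtrl`.
#' @param from,to interval index bounds (`from <= to`).
#' @param c symbol rank.
#' @param direction `"down"` (smallest index) or `"up"` (largest index).
#' @return interval index or `NA_integer_`.
#' @export
rank_select_next <- function(idx, from, to, c, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (c < 1L || c > length(idx$occ)) return(NA_integer_)
  v <- idx$occ[[c]]
  if (length(v) == 0L) return(NA_integer_)
  if (direction == "down") {
    j <- findInterval(from - 1L, v) + 1L
    if (j > length(v) || v[j] > to) NA_integer_ else v[j]
  } else {
    j <- findInterval(to, v)
    if (j < 1L || v[j] < from) NA_integer_ else v[j]
  }
}

#' New work counter for query instrumentation
#' @return environment with integer fields `lf`, `phi`, `phiinv`, `dict`.
#' @export
new_counter <- function() {
  ctr <- new.env(parent = emptyenv())
  ctr$lf <- 0L; ctr$phi <- 0L; ctr$phiinv <- 0L; ctr$dict <- 0L
  ctr
}

#' Total primitive operations recorded by a counter
#' @param ctr a counter environment.
#' @return integer total.
#' @export
counter_total <- function(ctr) ctr$lf + ctr$phi + ctr$phiinv + ctr$dict

#' Serialize an index to a versioned JSON container
#'
#' Human-readable, platform-independent container of named integer arrays.
#' @param idx an `optbwtrl`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_index <- function(idx, path) {
  ser_mv <- function(ms) list(p = ms$p, q = ms$q, succ = ms$succ,
                              samp = ms$samp, role = ms$role,
                              k = ms$k, n = ms$n, d = ms$d)
  obj <- list(
    format = "optbwtrl", version = 1L,
    n = idx$n, r = idx$r, d = idx$d,
    alphabet = idx$alphabet, sentinel_count = idx$sentinel_count,
    seq_names = idx$seq_names, seq_ends = idx$seq_ends,
    mv_lf = ser_mv(idx$mv_lf), mv_phi = ser_mv(idx$mv_phi),
    mv_phiinv = ser_mv(idx$mv_phiinv),
    Lfirst = idx$Lfirst, ND = idx$ND, PD = idx$PD,
    SAplus = idx$SAplus, SAminus = idx$SAminus,
    SAphi_plus = idx$SAphi_plus, SAphi_minus = idx$SAphi_minus,
    SAindex_plus = idx$SAindex_plus, SAindex_minus = idx$SAindex_minus)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load an index from a JSON container
#'
#' Rejects containers with a different format tag or version, and reports
#' corrupt files cleanly.
#' @param path file written by [save_index()].
#' @return an `optbwtrl`.
#' @export
load_index <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupt index container: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "optbwtrl") || !identical(as.integer(obj$version), 1L))
    stop("index container version mismatch (expected optbwtrl v1)")
  de_mv <- function(o) structure(
    list(p = as.integer(o$p), q = as.integer(o$q), k = as.integer(o$k),
         n = as.integer(o$n), d = as.integer(o$d),
         succ = as.integer(o$succ),
         samp = if (is.null(o$samp)) NULL else as.integer(o$samp),
         role = o$role),
    class = "move_structure")
  Lfirst <- as.integer(obj$Lfirst)
  sigma <- as.integer(obj$sentinel_count) + length(obj$alphabet)
  structure(
    list(mv_lf = de_mv(obj$mv_lf), mv_phi = de_mv(obj$mv_phi),
         mv_phiinv = de_mv(obj$mv_phiinv),
         Lfirst = Lfirst,
         occ = lapply(seq_len(sigma), function(cc) which(Lfirst == cc)),
         ND = as.integer(obj$ND), PD = as.integer(obj$PD),
         SAplus = as.integer(obj$SAplus), SAminus = as.integer(obj$SAminus),
         SAphi_plus = as.integer(obj$SAphi_plus),
         SAphi_minus = as.integer(obj$SAphi_minus),
         SAindex_plus = as.integer(obj$SAindex_plus),
         SAindex_minus = as.integer(obj$SAindex_minus),
         n = as.integer(obj$n), r = as.integer(obj$r), d = as.integer(obj$d),
         alphabet = as.character(obj$alphabet),
         sentinel_count = as.integer(obj$sentinel_count),
         seq_names = as.character(obj$seq_names),
         seq_ends = as.integer(obj$seq_ends)),
    class = "optbwtrl")
}
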