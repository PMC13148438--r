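#' Diagonal-keyed dictionaries of live text suffixes
#'
#' `dictocc` maps each text suffix currently inside the tracked sa-interval,
#' keyed by its diagonal (text suffix minus pattern alignment, possibly
#' negative), to the end position in the pattern of its longest match. Two
#' interchangeable backends:
#' * `"hashed"`: an R hashed environment — expected O(1) per operation;
#' * `"ordered"`: a sorted key vector with binary search — a deterministic
#'   logarithmic-class mapping.
#'
#' @param mode `"hashed"` or `"ordered"`.
#' @return an `occ_dict`.
#' @export
dict_new <- function(mode = c("hashed", "ordered")) {
  mode <- match.arg(mode)
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (mode == "ordered") { e$keys <- integer(0); e$vals <- integer(0) }
  structure(list(e = e, mode = mode), class = "occ_dict")
}

#' @rdname dict_new
#' @param d an `occ_dict`.
#' @param key integer diagonal key.
#' @param val integer value (match end in the pattern).
#' @export
dict_put <- function(d, key, val) {
  if (d$mode == "hashed") assign(as.character(key), val, envir = d$e)
  else {
    e <- d$e
    pos <- findInterval(key, e$keys)
    if (pos >= 1L && pos <= length(e$keys) && e$keys[pos] == key)
      e$vals[pos] <- val
    else {
      e$keys <- append(e$keys, key, after = pos)
      e$vals <- append(e$vals, val, after = pos)
    }
  }
  invisible(d)
}

#' @rdname dict_new
#' @export
dict_pop <- function(d, key) {
  if (d$mode == "hashed") {
    nm <- as.character(key)
    val <- get0(nm, envir = d$e, inherits = FALSE)
    if (is.null(val))
      stop("dictocc: missing key ", key, " (internal consistency error)")
    rm(list = nm, envir = d$e)
    val
  } else {
    e <- d$e
    pos <- findInterval(key, e$keys)
    if (pos < 1L || pos > length(e$keys) || e$keys[pos] != key)
      stop("dictocc: missing key ", key, " (internal consistency error)")
    val <- e$vals[pos]
    e$keys <- e$keys[-pos]
    e$vals <- e$vals[-pos]
    val
  }
}

#' @rdname dict_new
#' @export
dict_size <- function(d) {
  if (d$mode == "hashed") length(d$e) else length(d$e$keys)
}

#' Balanced sa_lcp-interval of the empty pattern
#'
#' The 13-tuple tracking the full suffix-array range `[1, n]` with its middle
#' pinned to the top row, assembled purely from index samples (`SA[1]` and
#' `SA[n]` are the first/last LF-interval samples).
#' @param idx an `optbwtrl`.
#' @return a `sa_lcp_interval`.
#' @export
root_interval <- function(idx) {
  k <- idx$mv_lf$k
  structure(
    list(b = 1L, d = 1L, e = idx$n,
         sab = idx$SAplus[1L], sad = idx$SAplus[1L], sae = idx$SAminus[k],
         i = 1L, j = 1L, k = k,
         v = idx$SAphi_plus[1L], w = idx$SAphi_plus[1L],
         x = idx$SAindex_plus[1L], y = idx$SAindex_minus[k]),
    class = "sa_lcp_interval")
}

#' @export
print.sa_lcp_interval <- function(x, ...) {
  cat(sprintf("sa_lcp-interval rows [%d, %d] (middle %d), SA = (%d, %d, %d)\n",
              x$b, x$e, x$d, x$sab, x$sad, x$sae))
  invisible(x)
}

# Nearest interval with symbol `cc` at or after `from` (capped at `hi`),
# or at or before `from` (floored at `lo`). The run_scan variant walks the
# ND/PD run-jump arrays; rank_select uses the occurrence lists.
next_c_interval <- function(idx, from, hi, cc, variant) {
  if (variant == "rank_select") return(rank_select_next(idx, from, hi, cc, "down"))
  Lf <- idx$Lfirst; nd <- idx$ND
  o <- from
  repeat {
    if (is.na(o) || o > hi) return(NA_integer_)
    if (Lf[o] == cc) return(o)
    o <- nd[o]
  }
}

prev_c_interval <- function(idx, from, lo, cc, variant) {
  if (variant == "rank_select") return(rank_select_next(idx, lo, from, cc, "up"))
  Lf <- idx$Lfirst; pd <- idx$PD
  o <- from
  repeat {
    if (is.na(o) || o < lo) return(NA_integer_)
    if (Lf[o] == cc) return(o)
    o <- pd[o]
  }
}

#' Backward extension of a balanced sa_lcp-interval
#'
#' Given the balanced sa_lcp-interval of a string `Q` occurring in the text and
#' a symbol `c`, returns the balanced sa_lcp-interval of `cQ`, or `NULL` if
#' `cQ` does not occur. The top, bottom and middle rows step through the LF
#' move structure when their BWT symbol already equals `c`; otherwise they jump
#' to the nearest interval with symbol `c` (found through the rank-select
#' occurrence lists or by walking the `ND`/`PD` run-jump arrays, per
#' `variant`) and reseed their suffix values and phi/phi-inverse interval
#' indices from the index samples. Both variants compute identical tuples.
#'
#' @param idx an `optbwtrl`.
#' @param itv a `sa_lcp_interval` for `Q`.
#' @param cc symbol rank (`c`).
#' @param variant `"run_scan"` (default: ND/PD walk, linear in the runs of the
#'   interval) or `"rank_select"`.
#' @param ctr optional work counter.
#' @return a `sa_lcp_interval` for `cQ`, or `NULL`.
#' @export
extend_interval <- function(idx, itv, cc, variant = c("run_scan", "rank_select"),
                            ctr = NULL) {
  variant <- match.arg(variant)
  Lf <- idx$Lfirst
  p_lf <- idx$mv_lf$p
  p_plus <- idx$mv_phi$p
  p_minus <- idx$mv_phiinv$p

  # --- top: b, SA[b], i, v
  if (!is.na(cc) && cc >= 1L && Lf[itv$i] == cc) {
    mv <- lf_step(idx, itv$b, itv$i, ctr)
    b2 <- mv[1L]; i2 <- mv[2L]
    sab2 <- itv$sab - 1L
    v2 <- if (itv$sab == p_plus[itv$v]) itv$v - 1L else itv$v
  } else {
    ihat <- if (is.na(cc) || cc < 1L) NA_integer_ else
      next_c_interval(idx, itv$i, itv$k, cc, variant)
    if (is.na(ihat)) return(NULL)
    bhat <- p_lf[ihat]
    mv <- lf_step(idx, bhat, ihat, ctr)
    b2 <- mv[1L]; i2 <- mv[2L]
    sab2 <- idx$SAplus[ihat] - 1L
    v2 <- idx$SAphi_plus[ihat] - 1L
  }

  # --- bottom: e, SA[e], k, y
  if (Lf[itv$k] == cc) {
    mv <- lf_step(idx, itv$e, itv$k, ctr)
    e2 <- mv[1L]; k2 <- mv[2L]
    sae2 <- itv$sae - 1L
    y2 <- if (itv$sae == p_minus[itv$y]) itv$y - 1L else itv$y
  } else {
    khat <- prev_c_interval(idx, itv$k, itv$i, cc, variant)
    ehat <- p_lf[khat + 1L] - 1L       # khat < k <= #intervals, so in range
    mv <- lf_step(idx, ehat, khat, ctr)
    e2 <- mv[1L]; k2 <- mv[2L]
    sae2 <- idx$SAminus[khat] - 1L
    y2 <- idx$SAindex_minus[khat] - 1L
  }

  # --- middle: d, SA[d], j, w, x
  if (Lf[itv$j] == cc) {
    mv <- lf_step(idx, itv$d, itv$j, ctr)
    d2 <- mv[1L]; j2 <- mv[2L]
    sad2 <- itv$sad - 1L
    w2 <- if (itv$sad == p_plus[itv$w]) itv$w - 1L else itv$w
    x2 <- if (itv$sad == p_minus[itv$x]) itv$x - 1L else itv$x
  } else {
    jhat <- prev_c_interval(idx, itv$j, itv$i, cc, variant)
    if (!is.na(jhat)) {
      # preceding c-interval: reseed like the bottom
      dhat <- p_lf[jhat + 1L] - 1L
      mv <- lf_step(idx, dhat, jhat, ctr)
      d2 <- mv[1L]; j2 <- mv[2L]
      sad2 <- idx$SAminus[jhat] - 1L
      x2 <- idx$SAindex_minus[jhat] - 1L
      wca <- idx$SAphi_minus[jhat]
      w2 <- if (idx$SAminus[jhat] == p_plus[wca]) wca - 1L else wca
    } else {
      # succeeding c-interval: reseed like the top
      jhat <- next_c_interval(idx, itv$j, itv$k, cc, variant)
      dhat <- p_lf[jhat]
      mv <- lf_step(idx, dhat, jhat, ctr)
      d2 <- mv[1L]; j2 <- mv[2L]
      sad2 <- idx$SAplus[jhat] - 1L
      w2 <- idx$SAphi_plus[jhat] - 1L
      xca <- idx$SAindex_plus[jhat]
      x2 <- if (idx$SAplus[jhat] == p_minus[xca]) xca - 1L else xca
    }
  }

  if (b2 > e2 || d2 < b2 || d2 > e2)
    stop("extend_interval: inconsistent tuple (caller bug)")
  structure(list(b = b2, d = d2, e = e2, sab = sab2, sad = sad2, sae = sae2,
                 i = i2, j = j2, k = k2, v = v2, w = w2, x = x2, y = y2),
            class = "sa_lcp_interval")
}

#' Emit matches walking up / down the suffix array
#'
#' `output_matches_up(s, iota, z)` emits `z` matches for the suffixes at and
#' above `s` in suffix-array order (reached by phi steps), reading each match
#' end from the diagonal dictionary and removing the key;
#' `output_matches_down` walks below `s` via phi-inverse steps. A missing key
#' signals an internal consistency error. Each emitted triple is the LEM
#' `P[f+1, g] = T[s, s + g - (f+1)]` with `g` the stored end.
#'
#' @param idx an `optbwtrl`.
#' @param dict an `occ_dict`.
#' @param s starting text suffix (live in `dict`).
#' @param iota phi (up) or phi-inverse (down) input interval of `s`.
#' @param z number of matches to emit (`>= 1`).
#' @param f current window start (the emitted matches start at `f + 1`).
#' @param emit function `(p_start, t_start, length)`.
#' @param ctr optional work counter.
#' @return `NULL`, invisibly.
#' @export
output_matches_up <- function(idx, dict, s, iota, z, f, emit, ctr = NULL) {
  repeat {
    if (!is.null(ctr)) ctr$dict <- ctr$dict + 1L
    g <- dict_pop(dict, s - (f + 1L))
    emit(f + 1L, s, g - f)
    z <- z - 1L
    if (z == 0L) break
    st <- phi_step(idx, s, iota, ctr)
    s <- st[1L]; iota <- st[3L]
  }
  invisible(NULL)
}

#' @rdname output_matches_up
#' @export
output_matches_down <- function(idx, dict, s, iota, z, f, emit, ctr = NULL) {
  repeat {
    if (!is.null(ctr)) ctr$dict <- ctr$dict + 1L
    g <- dict_pop(dict, s - (f + 1L))
    emit(f + 1L, s, g - f)
    z <- z - 1L
    if (z == 0L) break
    st <- phi_inv_step(idx, s, iota, ctr)
    s <- st[1L]; iota <- st[3L]
  }
  invisible(NULL)
}

# Output sweep of one advancement: emit every suffix of `itv` whose BWT symbol
# differs from `cc` (the next pattern symbol; cc = 0 matches nothing and
# flushes everything). Walks the LF input intervals i..k, skipping runs of
# `cc` through ND.
sweep_output <- function(idx, itv, dict, cc, f, emit, ctr) {
  Lf <- idx$Lfirst
  p_lf <- idx$mv_lf$p
  i <- itv$i; k <- itv$k
  if (i == k) {
    if (Lf[i] != cc) {
      output_matches_up(idx, dict, itv$sad, itv$w, itv$d - itv$b + 1L, f, emit, ctr)
      if (itv$e > itv$d) {
        st <- phi_inv_step(idx, itv$sad, itv$x, ctr)
        output_matches_down(idx, dict, st[1L], st[3L], itv$e - itv$d, f, emit, ctr)
      }
    }
    return(invisible(NULL))
  }
  if (Lf[i] != cc)
    output_matches_up(idx, dict, idx$SAminus[i], idx$SAphi_minus[i],
                      p_lf[i + 1L] - itv$b, f, emit, ctr)
  o <- if (Lf[i] == cc) idx$ND[i] else i + 1L
  while (o < k) {
    if (Lf[o] == cc) o <- idx$ND[o]
    else {
      output_matches_down(idx, dict, idx$SAplus[o], idx$SAindex_plus[o],
                          p_lf[o + 1L] - p_lf[o], f, emit, ctr)
      o <- o + 1L
    }
  }
  if (o == k && Lf[k] != cc)
    output_matches_down(idx, dict, idx$SAplus[k], idx$SAindex_plus[k],
                        itv$e - p_lf[k] + 1L, f, emit, ctr)
  invisible(NULL)
}

# Expand a balanced sa_lcp-interval of P[f, f+L-1] outward while the LCP at
# the boundary stays >= L, inserting each adopted suffix into the dictionary
# with match end f+L-1. Returns the expanded tuple.
expand_interval <- function(idx, itv, dict, f, L, ctr) {
  p_lf <- idx$mv_lf$p
  k_lf <- idx$mv_lf$k
  b <- itv$b; sab <- itv$sab; i <- itv$i; v <- itv$v
  repeat {
    st <- phi_step(idx, sab, v, ctr)       # st[2] = PLCP[sab] = LCP[b]
    if (st[2L] < L) break
    if (b == p_lf[i]) i <- i - 1L
    b <- b - 1L
    sab <- st[1L]; v <- st[3L]
    if (!is.null(ctr)) ctr$dict <- ctr$dict + 1L
    dict_put(dict, sab - f, f + L - 1L)
  }
  e <- itv$e; sae <- itv$sae; k <- itv$k; y <- itv$y
  repeat {
    st <- phi_inv_step(idx, sae, y, ctr)   # st[2] = PLCP[phi_inv(sae)] = LCP[e+1]
    if (st[2L] < L) break
    if (e == (if (k < k_lf) p_lf[k + 1L] else idx$n + 1L) - 1L) k <- k + 1L
    e <- e + 1L
    sae <- st[1L]; y <- st[3L]
    if (!is.null(ctr)) ctr$dict <- ctr$dict + 1L
    dict_put(dict, sae - f, f + L - 1L)
  }
  itv$b <- b; itv$sab <- sab; itv$i <- i; itv$v <- v
  itv$e <- e; itv$sae <- sae; itv$k <- k; itv$y <- y
  itv
}

# Single-row tuple used when reseeding from matching statistics or from a
# seed_window() middle row.
collapsed_interval <- function(row, suff, lf_int, phi_int, phiinv_int) {
  structure(list(b = row, d = row, e = row, sab = suff, sad = suff, sae = suff,
                 i = lf_int, j = lf_int, k = lf_int,
                 v = phi_int, w = phi_int, x = phiinv_int, y = phiinv_int),
            class = "sa_lcp_interval")
}

#' One long sa_lcp-interval advancement
#'
#' Given the balanced sa_lcp-interval of `P[f+1, f+L]` (or `NULL`) and the
#' diagonal dictionary of its suffixes, (1) emits every long LEM of the form
#' `P[f+1, g]` by sweeping the interval's LF runs, (2) extends the interval by
#' `P[f]`, reseeding from the matching statistics (or a window seeder) when the
#' extension is empty, and (3) expands the result to the interval of
#' `P[f, f+L-1]`, inserting the adopted suffixes. Runs in expected time
#' proportional to the number of matches emitted plus suffixes adopted.
#'
#' @param idx an `optbwtrl`.
#' @param itv interval of `P[f+1, f+L]` or `NULL`.
#' @param dict the `occ_dict` for `itv` (keys = its suffixes on diagonals).
#' @param pat integer pattern ranks.
#' @param f window start being advanced to.
#' @param L threshold.
#' @param emit emission callback.
#' @param reseed function `(f)` returning a collapsed single-row tuple for
#'   `P[f, f+L-1]` (already inserted into `dict`) or `NULL` if the window does
#'   not occur.
#' @param variant extension variant.
#' @param ctr optional work counter.
#' @return the interval of `P[f, f+L-1]`, or `NULL`.
#' @export
advance <- function(idx, itv, dict, pat, f, L, emit, reseed,
                    variant = "run_scan", ctr = NULL) {
  cc <- pat[f]
  if (!is.null(itv)) {
    sweep_output(idx, itv, dict, cc, f, emit, ctr)
    itv2 <- extend_interval(idx, itv, cc, variant = variant, ctr = ctr)
  } else itv2 <- NULL
  if (is.null(itv2)) itv2 <- reseed(f)
  if (is.null(itv2)) return(NULL)
  expand_interval(idx, itv2, dict, f, L, ctr)
}

#' Report all long LEMs of a pattern, given matching statistics
#'
#' Iterates the advancement from the last length-`L` window of the pattern down
#' to the first, then flushes the surviving dictionary entries (the matches
#' touching the pattern's left edge). Output is the exact set of locally
#' maximal exact matches of length at least `L`, without duplicates, in
#' expected time linear in the pattern length plus the number of matches.
#'
#' @param idx an `optbwtrl`.
#' @param pattern integer ranks (see [map_pattern()]) or a string.
#' @param ms augmented matching statistics of the pattern ([augment_ms()]).
#' @param L length threshold (`>= 1`).
#' @param variant extension variant, `"run_scan"` or `"rank_select"`.
#' @param dict_mode `"hashed"` or `"ordered"`.
#' @param check if `TRUE`, assert after every advancement that the dictionary
#'   size equals the interval width (costs a dictionary-size query per window).
#' @return data.frame `p_start`, `t_start`, `length` (sorted); attribute
#'   `"work"` holds the primitive-operation counts.
#' @export
long_lem_query <- function(idx, pattern, ms, L,
                           variant = c("run_scan", "rank_select"),
                           dict_mode = c("hashed", "ordered"),
                           check = FALSE) {
  variant <- match.arg(variant)
  dict_mode <- match.arg(dict_mode)
  if (L < 1L) stop("threshold L must be >= 1")
  pat <- as.integer(pattern)
  stopifnot(length(pat) == ms$m)
  if (is.null(ms$i)) stop("matching statistics must be augmented (augment_ms)")
  ctr <- new_counter()
  reseed_raw <- function(f) {
    if (is.na(ms$len[f]) || ms$len[f] != L) return(NULL)
    ctr$dict <- ctr$dict + 1L
    collapsed_interval(ms$row[f], ms$suff[f], ms$i[f], ms$w[f], ms$x[f])
  }
  run_long_lem_with_seed(idx, pat, L, reseed_raw, variant, dict_mode, check, ctr)
}

# internal: binds the reseed callback to the live dictionary
run_long_lem_with_seed <- function(idx, pat, L, reseed_raw, variant, dict_mode,
                                   check, ctr) {
  # The dictionary lives inside run_long_lem; thread the seed insertion by
  # composing reseed with a put on the same dict via a shared cell.
  cell <- new.env(parent = emptyenv())
  reseed <- function(f) {
    out <- reseed_raw(f)
    if (!is.null(out)) dict_put(cell$dict, out$sad - f, f + L - 1L)
    out
  }
  run_long_lem2(idx, pat, L, reseed, variant, dict_mode, check, ctr, cell)
}

run_long_lem2 <- function(idx, pat, L, reseed, variant, dict_mode, check, ctr,
                          cell) {
  m <- length(pat)
  acc <- new.env(parent = emptyenv())
  acc$p <- integer(64L); acc$t <- integer(64L); acc$l <- integer(64L); acc$n <- 0L
  emit <- function(p_start, t_start, len) {
    nn <- acc$n + 1L
    if (nn > length(acc$p)) {
      acc$p <- c(acc$p, integer(length(acc$p)))
      acc$t <- c(acc$t, integer(acc$n))
      acc$l <- c(acc$l, integer(acc$n))
    }
    acc$p[nn] <- p_start; acc$t[nn] <- t_start; acc$l[nn] <- len
    acc$n <- nn
  }
  dict <- dict_new(dict_mode)
  cell$dict <- dict
  itv <- NULL
  if (L <= m && m > 0L) {
    for (f in seq(m - L + 1L, 1L)) {
      itv <- advance(idx, itv, dict, pat, f, L, emit, reseed, variant, ctr)
      if (check) {
        width <- if (is.null(itv)) 0L else itv$e - itv$b + 1L
        if (dict_size(dict) != width)
          stop("dictionary size ", dict_size(dict),
               " does not match interval width ", width, " at f = ", f)
      }
    }
    if (!is.null(itv)) sweep_output(idx, itv, dict, 0L, 0L, emit, ctr)
  }
  if (dict_size(dict) != 0L)
    stop("dictionary not empty after the final flush (internal error)")
  nn <- acc$n
  out <- data.frame(p_start = acc$p[seq_len(nn)], t_start = acc$t[seq_len(nn)],
                    length = acc$l[seq_len(nn)])
  out <- out[order(out$p_start, out$t_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "work") <- list(lf = ctr$lf, phi = ctr$phi, phiinv = ctr$phiinv,
                            dict = ctr$dict,
                            total = counter_total(ctr))
  out
}

#' Report all long LEMs without precomputed matching statistics
#'
#' Identical output to [long_lem_query()], but whenever the advancing interval
#' empties, the next window's interval is recomputed from scratch by
#' [seed_window()] (`L` backward extension steps), instead of consulting
#' matching statistics — the direct variant, linear in pattern length times
#' threshold plus output size.
#'
#' @inheritParams long_lem_query
#' @export
long_lem_query_direct <- function(idx, pattern, L,
                                  variant = c("run_scan", "rank_select"),
                                  dict_mode = c("hashed", "ordered"),
                                  check = FALSE) {
  variant <- match.arg(variant)
  dict_mode <- match.arg(dict_mode)
  if (L < 1L) stop("threshold L must be >= 1")
  pat <- as.integer(pattern)
  ctr <- new_counter()
  reseed_raw <- function(f) {
    win <- seed_window(idx, pat, f, L, variant = variant, ctr = ctr)
    if (is.null(win)) return(NULL)
    if (!is.null(ctr)) ctr$dict <- ctr$dict + 1L
    collapsed_interval(win$d, win$sad, win$j, win$w, win$x)
  }
  run_long_lem_with_seed(idx, pat, L, reseed_raw, variant, dict_mode,
                         check, ctr)
}
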