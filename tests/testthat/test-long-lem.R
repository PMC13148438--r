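# Oracle sa-interval of a string: rows whose suffixes start with it.
oracle_interval <- function(st, q) {
  n <- st$text$n
  rows <- which(vapply(seq_len(n), function(r) {
    s <- st$SA[r]
    s + length(q) - 1L <= n && all(st$text$symbols[s:(s + length(q) - 1L)] == q)
  }, logical(1)))
  if (length(rows) == 0L) NULL else c(min(rows), max(rows))
}

test_that("backward extension follows the worked example", {
  tx <- toy_text()
  idx <- build_index(tx)
  pat <- map_pattern(tx, "aab")
  itv_ab <- seed_window(idx, pat, 2L, 2L)             # "ab" -> rows [3,4]
  got <- extend_interval(idx, itv_ab, pat[1L])        # "aab" -> rows [2,2]
  expect_identical(c(got$b, got$e), c(2L, 2L))
  expect_identical(c(got$sab, got$sae), c(3L, 3L))
  # extending by a symbol with no occurrence in the interval's BWT span:
  # "aaab" does not occur ("aab" row has BWT symbol 'b', no adjacent 'a' run)
  expect_null(extend_interval(idx, got, map_pattern(tx, "a")[1L]))
  expect_null(extend_interval(idx, got, 0L))          # unknown symbol
})

test_that("both extension variants agree with each other and the oracle", {
  cases <- 0L
  for (seed in 1:8) {
    tx <- if (seed %% 2L)
      random_text(sample(10:150, 1), sigma = 2L, seed = 110L + seed)
    else simulate_panel(sample(2:5, 1), sample(20:60, 1), 0.05,
                        seed = 110L + seed)$text
    st <- build_suffix_structures(tx)
    idx <- build_index(tx, d = sample(2:3, 1))
    sigma <- tx$sentinel_count + length(tx$alphabet)
    set.seed(130L + seed)
    for (rep in 1:40) {
      # random occurring substring Q, random extension symbol c
      s0 <- sample(tx$n, 1L)
      ql <- sample.int(min(6L, tx$n - s0 + 1L), 1L)
      q <- tx$symbols[s0:(s0 + ql - 1L)]
      if (any(q <= tx$sentinel_count)) next
      cc <- sample((tx$sentinel_count + 1L):sigma, 1L)
      # build the tuple for Q via extensions (rank_select), then extend by cc
      itv <- root_interval(idx)
      for (pos in seq(ql, 1L)) itv <- extend_interval(idx, itv, q[pos], "rank_select")
      e1 <- extend_interval(idx, itv, cc, "rank_select")
      e2 <- extend_interval(idx, itv, cc, "run_scan")
      want <- oracle_interval(st, c(cc, q))
      cases <- cases + 1L
      if (is.null(want)) {
        expect_null(e1); expect_null(e2)
      } else {
        expect_identical(unclass(e1), unclass(e2))
        expect_identical(c(e1$b, e1$e), want)
        expect_identical(e1$sab, st$SA[e1$b])
        expect_identical(e1$sae, st$SA[e1$e])
        expect_identical(e1$sad, st$SA[e1$d])
        expect_true(e1$b <= e1$d && e1$d <= e1$e)
        # interval indices consistent
        expect_identical(e1$i, interval_of(idx$mv_lf, e1$b))
        expect_identical(e1$j, interval_of(idx$mv_lf, e1$d))
        expect_identical(e1$k, interval_of(idx$mv_lf, e1$e))
        expect_identical(e1$v, interval_of(idx$mv_phi, e1$sab))
        expect_identical(e1$w, interval_of(idx$mv_phi, e1$sad))
        expect_identical(e1$x, interval_of(idx$mv_phiinv, e1$sad))
        expect_identical(e1$y, interval_of(idx$mv_phiinv, e1$sae))
      }
    }
  }
  expect_gt(cases, 100L)
})

test_that("output_matches emits the stored match and empties the dictionary", {
  tx <- toy_text()
  idx <- build_index(tx)
  dict <- dict_new("hashed")
  dict_put(dict, -1L, 3L)                 # suffix 1 at window f = 1
  got <- list()
  emit <- function(p, t, l) got[[length(got) + 1L]] <<- c(p, t, l)
  output_matches_up(idx, dict, 1L, interval_of(idx$mv_phi, 1L), 1L, 1L, emit)
  expect_identical(got[[1L]], c(2L, 1L, 2L))
  expect_identical(dict_size(dict), 0L)
  expect_error(output_matches_up(idx, dict, 1L, 1L, 1L, 1L, emit), "missing key")
})

test_that("one advancement reproduces the hand trace on the toy example", {
  tx <- toy_text()
  idx <- build_index(tx)
  pat <- map_pattern(tx, "aab")
  st <- build_suffix_structures(tx)
  ms <- augment_ms(idx, compute_ms_oracle(st, pat))
  dict <- dict_new("hashed")
  dict_put(dict, 2L, 3L); dict_put(dict, -1L, 3L)   # suffixes 4 and 1 at f=2
  itv <- seed_window(idx, pat, 2L, 2L)              # rows [3,4] of "ab"
  got <- list()
  emit <- function(p, t, l) got[[length(got) + 1L]] <<- c(p, t, l)
  reseed <- function(f) NULL
  out <- advance(idx, itv, dict, pat, 1L, 2L, emit, reseed)
  expect_identical(got[[1L]], c(2L, 1L, 2L))        # P[2,3] = T[1,2]
  expect_identical(c(out$b, out$e), c(2L, 2L))
  expect_identical(dict_size(dict), 1L)
  expect_identical(dict_pop(dict, 2L), 3L)
})

test_that("the full query returns exactly the worked-example triples", {
  tx <- toy_text()
  idx <- build_index(tx)
  pat <- map_pattern(tx, "aab")
  ms <- augment_ms(idx, compute_ms_oracle(build_suffix_structures(tx), pat))
  want <- data.frame(p_start = c(1L, 2L), t_start = c(3L, 1L), length = c(3L, 2L))
  for (vr in c("run_scan", "rank_select")) for (dm in c("hashed", "ordered")) {
    expect_same_triples(long_lem_query(idx, pat, ms, 2L, vr, dm, check = TRUE), want)
    expect_same_triples(long_lem_query_direct(idx, pat, 2L, vr, dm, check = TRUE), want)
  }
  expect_identical(nrow(long_lem_query(idx, pat, ms, 4L)), 0L)   # L = m + 1
  expect_error(long_lem_query(idx, pat, ms, 0L), "L must be")
})

test_that("an exact substring pattern reports the whole-pattern match", {
  tx <- toy_text()
  idx <- build_index(tx)
  pat <- map_pattern(tx, "baab")        # T[2,5]
  ms <- augment_ms(idx, compute_ms_oracle(build_suffix_structures(tx), pat))
  res <- long_lem_query(idx, pat, ms, 3L)
  expect_true(any(res$p_start == 1L & res$t_start == 2L & res$length == 4L))
})

test_that("query output equals the brute-force oracle across random instances", {
  for (seed in 1:12) {
    sim <- simulate_panel(sample(2:6, 1), sample(20:90, 1),
                          sample(c(0.005, 0.03, 0.15), 1), seed = 140L + seed)
    tx <- sim$text
    idx <- build_index(tx)
    st <- build_suffix_structures(tx)
    pat <- map_pattern(tx, sim$pattern)
    ms <- augment_ms(idx, compute_ms_oracle(st, pat))
    for (L in c(2L, 5L, 11L)) {
      want <- enumerate_lems_bruteforce(tx, pat, L)
      got <- long_lem_query(idx, pat, ms, L, check = TRUE)
      expect_same_triples(got, want)
      gotd <- long_lem_query_direct(idx, pat, L, check = TRUE)
      expect_same_triples(gotd, want)
    }
  }
})

test_that("patterns with symbols absent from the text are handled", {
  tx <- toy_text()
  idx <- build_index(tx)
  pat <- map_pattern(tx, "azab")
  ms <- augment_ms(idx, compute_ms_oracle(build_suffix_structures(tx), pat))
  want <- enumerate_lems_bruteforce(tx, pat, 2L)
  expect_same_triples(long_lem_query(idx, pat, ms, 2L, check = TRUE), want)
  expect_same_triples(long_lem_query_direct(idx, pat, 2L, check = TRUE), want)
  # empty pattern
  mse <- augment_ms(idx, compute_ms_oracle(build_suffix_structures(tx), integer(0)))
  expect_identical(nrow(long_lem_query(idx, integer(0), mse, 2L)), 0L)
  expect_identical(nrow(long_lem_query_direct(idx, integer(0), 2L)), 0L)
})

test_that("work scales linearly in pattern length plus output size", {
  ratios <- numeric(0)
  for (seed in 1:10) {
    sim <- simulate_panel(sample(3:10, 1), sample(50:200, 1),
                          sample(c(0.002, 0.01, 0.05), 1), seed = 160L + seed)
    idx <- build_index(sim$text)
    st <- build_suffix_structures(sim$text)
    pat <- map_pattern(sim$text, sim$pattern)
    ms <- augment_ms(idx, compute_ms_oracle(st, pat))
    for (L in c(4L, 8L, 16L)) {
      res <- long_lem_query(idx, pat, ms, L)
      w <- attr(res, "work")
      ratios <- c(ratios, w$total / (length(pat) + nrow(res)))
    }
  }
  # fixed constant chosen from the per-step accounting of the algorithm
  expect_true(all(ratios <= 64))
})
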