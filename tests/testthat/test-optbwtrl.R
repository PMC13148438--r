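test_that("the toy index components match hand-derived values", {
  idx <- build_index(toy_text())
  expect_identical(idx$r, 4L)
  expect_identical(idx$Lfirst, c(3L, 2L, 1L, 2L))      # "ba$a"
  expect_identical(idx$ND, c(2L, 3L, 4L, 5L))
  expect_identical(idx$PD, c(-1L, 1L, 2L, 3L))
  expect_identical(idx$SAplus, c(6L, 4L, 1L, 5L))
  expect_identical(idx$SAminus, c(3L, 4L, 1L, 2L))
  expect_identical(idx$mv_phi$p, c(1L, 4L, 5L, 6L))
  expect_identical(idx$mv_phi$samp, c(2L, 1L, 0L, 0L))
  expect_identical(idx$mv_phiinv$p, c(1L, 2L, 3L, 4L))
  expect_identical(idx$mv_phiinv$samp, c(0L, 0L, 1L, 2L))
})

test_that("a minimal two-run text yields arrays of length two", {
  idx <- build_index(text_from_strings("a"))   # "a$"
  expect_identical(idx$r, 2L)
  for (nm in c("Lfirst", "ND", "PD", "SAplus", "SAminus"))
    expect_length(idx[[nm]], 2L)
})

test_that("sample cross-references are mutually consistent", {
  for (seed in 1:5) {
    sim <- simulate_panel(sample(2:6, 1), sample(30:100, 1), 0.02, seed = 600L + seed)
    idx <- build_index(sim$text)
    k <- idx$mv_lf$k
    pp <- idx$mv_phi$p; pm <- idx$mv_phiinv$p
    expect_identical(idx$SAphi_plus, findInterval(idx$SAplus, pp))
    expect_identical(idx$SAindex_minus, findInterval(idx$SAminus, pm))
    # p+_{SAphi_plus[i]} <= SAplus[i] < p+_{SAphi_plus[i]+1}
    expect_true(all(pp[idx$SAphi_plus] <= idx$SAplus))
    hi <- c(pp, idx$n + 1L)[idx$SAphi_plus + 1L]
    expect_true(all(idx$SAplus < hi))
    # every LF input interval lies within one BWT run
    st <- build_suffix_structures(sim$text)
    p_lf <- idx$mv_lf$p
    ends <- c(p_lf[-1L] - 1L, idx$n)
    run_of <- findInterval(seq_len(idx$n), st$rlbwt$start)
    expect_true(all(run_of[p_lf] == run_of[ends]))
    expect_identical(idx$Lfirst, st$BWT[p_lf])
    # every run-bottom suffix starts a phi-inverse input interval
    bot <- c(st$rlbwt$start[-1L] - 1L, idx$n)
    expect_true(all(st$SA[bot] %in% pm))
  }
})

test_that("index stepping agrees with oracle LF, phi, phi-inverse and PLCP", {
  for (seed in 1:8) {
    tx <- if (seed <= 4L) random_text(sample(2:200, 1), sigma = 2L, seed = 700L + seed)
          else simulate_panel(sample(2:5, 1), sample(20:80, 1), 0.05,
                              seed = 700L + seed)$text
    st <- build_suffix_structures(tx)
    idx <- build_index(tx)
    n <- tx$n
    # lf_step across all rows
    x <- 1L; got <- integer(n)
    for (i in seq_len(n)) {
      if (x < idx$mv_lf$k && i >= idx$mv_lf$p[x + 1L]) x <- x + 1L
      got[i] <- lf_step(idx, i, x)[1L]
    }
    expect_identical(got, st$LF)
    # phi_step and phi_inv_step across all suffixes
    w <- 1L; xx <- 1L
    gphi <- integer(n); gplcp <- integer(n); ginv <- integer(n); gbelow <- integer(n)
    for (s in seq_len(n)) {
      if (w < idx$mv_phi$k && s >= idx$mv_phi$p[w + 1L]) w <- w + 1L
      if (xx < idx$mv_phiinv$k && s >= idx$mv_phiinv$p[xx + 1L]) xx <- xx + 1L
      ps <- phi_step(idx, s, w)
      gphi[s] <- ps[1L]; gplcp[s] <- ps[2L]
      pi <- phi_inv_step(idx, s, xx)
      ginv[s] <- pi[1L]; gbelow[s] <- pi[2L]
    }
    expect_identical(gphi, st$phi)
    expect_identical(gplcp, st$PLCP)
    expect_identical(ginv, st$phi_inv)
    expect_identical(gbelow, st$PLCP[st$phi_inv])
  }
})

test_that("phi_step then phi_inv_step returns to the same suffix", {
  idx <- build_index(toy_text())
  expect_identical(phi_step(idx, 1L, 1L)[1:2], c(4L, 2L))  # phi(1)=4, PLCP[1]=2
  expect_identical(phi_step(idx, 3L, 1L)[1:2], c(6L, 0L))
  expect_identical(phi_inv_step(idx, 4L, 4L)[1:2], c(1L, 2L))
  expect_identical(phi_inv_step(idx, 5L, 4L)[1:2], c(2L, 1L))
  st <- phi_step(idx, 4L, 2L)
  back <- phi_inv_step(idx, st[1L], interval_of(idx$mv_phiinv, st[1L]))
  expect_identical(back[1L], 4L)
})

test_that("an LF walk from the sentinel row is a full cycle", {
  idx <- build_index(toy_text())
  row <- 4L; x <- interval_of(idx$mv_lf, row)    # row of suffix 1
  seen <- integer(0)
  for (i in 1:6) {
    seen <- c(seen, row)
    mv <- lf_step(idx, row, x); row <- mv[1L]; x <- mv[2L]
  }
  expect_identical(sort(seen), 1:6)
  expect_identical(row, 4L)
})

test_that("rank-select over Lfirst finds nearest symbol intervals", {
  idx <- build_index(toy_text())   # Lfirst = b a $ a
  a <- 2L; z <- 99L
  expect_identical(rank_select_next(idx, 1L, 4L, a, "down"), 2L)
  expect_identical(rank_select_next(idx, 1L, 4L, a, "up"), 4L)
  expect_identical(rank_select_next(idx, 3L, 3L, a, "down"), NA_integer_)
  expect_identical(rank_select_next(idx, 1L, 4L, z, "down"), NA_integer_)
})

test_that("ND jumps visit exactly the run-character changes", {
  for (seed in 1:4) {
    tx <- random_text(sample(5:150, 1), sigma = 3L, seed = 720L + seed)
    idx <- build_index(tx)
    o <- 1L; visited <- integer(0)
    while (o <= idx$mv_lf$k) { visited <- c(visited, o); o <- idx$ND[o] }
    Lf <- idx$Lfirst
    expected <- which(c(TRUE, Lf[-1L] != Lf[-length(Lf)]))
    expect_identical(visited, expected)
  }
})

test_that("index size scales with balanced interval count, not text length", {
  counts <- integer(0); intervals <- integer(0); ns <- integer(0)
  for (nh in c(5L, 10L, 20L)) {
    sim <- simulate_panel(nh, 400L, 0.002, seed = 800L)
    idx <- build_index(sim$text)
    counts <- c(counts, index_element_count(idx))
    intervals <- c(intervals, idx$mv_lf$k + idx$mv_phi$k + idx$mv_phiinv$k)
    ns <- c(ns, idx$n)
  }
  # a fixed small multiple of the interval count ...
  expect_true(all(counts <= 8L * intervals))
  # ... and strongly sublinear in n: quadrupling the panel (and n) must not
  # come close to quadrupling the stored elements on a near-identical panel
  expect_gt(ns[3L] / ns[1L], 3.9)
  expect_lt(counts[3L] / counts[1L], 2)
})

test_that("serialization round-trips losslessly and rejects bad containers", {
  idx <- build_index(simulate_panel(3L, 60L, 0.05, seed = 5L)$text, d = 3L)
  path <- tempfile(fileext = ".json")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_equal(idx2, idx)
  expect_identical(idx2$d, 3L)

  # truncated file
  raw <- readLines(path, warn = FALSE)
  trunc <- tempfile(fileext = ".json")
  writeLines(substr(paste(raw, collapse = ""), 1L, 50L), trunc)
  expect_error(load_index(trunc), "corrupt")

  # version mismatch
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$version <- 2L
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_index(bad), "version mismatch")
})
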