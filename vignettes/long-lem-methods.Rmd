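---
title: "Long LEM queries on a run-length compressed BWT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long LEM queries on a run-length compressed BWT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemindex)
```

## The match model

`lemindex` reports **locally maximal exact matches (LEMs)** between a query
pattern `P` (length `m`) and an indexed text `T` (length `n`, one or more
sequences each closed by its own sentinel). A match `P[i, j] = T[i', j']` is a
LEM when it cannot be extended simultaneously on either side — it is blocked
on the left by a pattern edge, a text edge, or a disagreeing preceding symbol,
and likewise on the right. On a fixed pattern-vs-text diagonal the LEMs are
exactly the maximal runs of agreement, which is what the package's brute-force
oracle (`enumerate_lems_bruteforce`) enumerates directly. Classical MEMs
(matches unextendable *in the pattern*) are a subset. Only LEMs of length at
least a threshold `L` ("long LEMs") are reported; without a threshold the
output can be quadratic in the input.

Sentinels make the sequence structure self-enforcing: each sequence ends in a
unique sentinel symbol ranked below every regular symbol, a pattern can never
contain one, and therefore no reported match spans a sequence boundary; a
match abutting a sentinel is automatically left-blocked because the sentinel
cannot equal any pattern symbol.

## Index structure

Construction (`build_index`) computes the uncompressed suffix structures once
— suffix array by prefix doubling, PLCP by Kasai's amortized scan — and then
discards them, retaining only run-length-scale components:

* a **move data structure** per permutation. A permutation of `[1, n]` whose
  value minus position is piecewise constant on `k` intervals is stored as
  the interval starts and their images; evaluating it is one offset addition
  plus locating the destination interval. Balancing (below) bounds that
  location step. LF has one conserved interval per BWT run; φ (suffix above
  in suffix-array order) is linear between consecutive run-top suffix
  values, and φ⁻¹ between consecutive run-bottom suffix values, so all three
  cost O(r) words for a BWT with `r` runs.
* **PLCP samples.** Within a φ input interval, `PLCP` decreases by exactly 1
  per position, so one sample per interval start (`LCP+`) turns a φ lookup
  into a simultaneous `PLCP[i]` query. Symmetrically, samples of
  `PLCP[phi_inv(p)]` (`LCP-`) on the φ⁻¹ structure answer "the LCP directly
  below row of suffix i". Both identities hold across balancing because
  splitting refines intervals and the samples are re-taken at the refined
  starts.
* **BWT run summaries** over the LF intervals: the symbol per interval
  (`Lfirst`), per-symbol occurrence lists for rank-select jumps, `ND`/`PD`
  run-change jumps, suffix-array samples at interval starts and ends, and
  the φ/φ⁻¹ interval indices of those samples. These let the query leave an
  interval and re-enter a neighbouring run without ever consulting a plain
  suffix array — the index keeps none.

### Balancing

A move query lands in an output interval and must find which input interval
contains the destination. The sequence is *balanced* with parameter `d`
(default 2, integer ≥ 2) by splitting pairs until every output interval
overlaps at most `2d - 1` input intervals: while a violator exists, its pair
is split at the position aligned with the d-th input-interval start inside
its output interval, so the first part overlaps exactly `d` intervals.
Iterating to a fixpoint yields at most `k + ceiling(k / (d-1))` intervals
(`2k` for `d = 2`) — asserted, together with preservation of the bijection,
over random permutations in the test suite. Larger `d` trades a slightly
smaller structure for a longer (still constant) scan; the default `d = 2` is
used everywhere unless a caller overrides it.

## The query

The query maintains, for the current length-`L` window of the pattern, a
**balanced sa_lcp-interval**: the 13-tuple
`(b, d, e, SA[b], SA[d], SA[e], i, j, k, v, w, x, y)` holding the window's
suffix-array interval `[b, e]`, a middle row `d`, and the move-structure
interval indices of the three rows (LF: `i, j, k`) and their suffix values
(φ: `v, w`; φ⁻¹: `x, y`). The companion dictionary `dictocc` maps the
diagonal `SA[a] - f_alignment` of every row in `[b, e]` to the end position
in the pattern of that suffix's longest match. Diagonal keys are what make
left-extension free: stepping the window left moves both the suffix and the
alignment by one, so carried entries keep their keys unchanged. Keys may be
negative; each text suffix occurs at most once in the interval, so keys are
unique.

One **advancement** from window `P[f+1, f+L]` to `P[f, f+L-1]`:

1. *Emit.* Sweep the LF intervals `i..k`. Runs whose symbol equals `P[f]`
   are skipped in one `ND` jump; every other suffix's match cannot extend
   left, so it is a LEM ending here: pop its diagonal and emit. The sweep
   walks suffixes with φ steps (upward, for the partial top interval) and
   φ⁻¹ steps (downward, for middle/bottom intervals), starting from the
   boundary suffix-array samples.
2. *Extend.* Backward-extend the tuple by `P[f]`. Rows whose BWT symbol
   already equals `P[f]` take one LF step and decrement their φ/φ⁻¹ interval
   index exactly when they sat on an interval start. Otherwise the row jumps
   to the nearest `P[f]` interval — found either through the rank-select
   occurrence lists or by an `ND`/`PD` walk (two variants, cross-checked to
   produce identical tuples) — and reseeds its fields from the boundary
   samples. The middle row prefers a preceding interval (reseeding like the
   bottom) and falls back to a succeeding one (reseeding like the top), which
   keeps `b ≤ d ≤ e` because LF preserves the order of equal-symbol rows.
3. *Reseed if empty.* If the extension died, every dictionary entry was
   emitted in step 1 and the new window occurs only if its matching
   statistic is exactly `L`; in that case the tuple restarts as a single row
   taken from the augmented matching statistics (`row`, `suff`, and its
   three interval indices), or, in the direct mode, from an `L`-step
   backward search (`seed_window`). The restart row is collapsed to
   `b = d = e`, which is sufficient because expansion regrows the interval.
4. *Expand.* Grow the interval upward while `PLCP[SA[b]] ≥ L` and downward
   while `PLCP[phi_inv(SA[e])] ≥ L` — each test is one φ (resp. φ⁻¹) step
   that also delivers the next suffix value — inserting every adopted
   suffix with match end `f + L - 1` (its LCP with the new window suffix is
   exactly `L`, else it would have survived the extension).

Iterating `f` from `m - L + 1` down to 1 and finally flushing (a sweep with a
symbol that matches nothing: every surviving entry is a LEM touching the
pattern's left edge) emits every long LEM exactly once. Each advancement
costs O(matches emitted + suffixes adopted) primitive steps, so a whole query
is O(m + occ) expected time with the hashed dictionary. The test suite
asserts a concrete proxy: total LF/φ/φ⁻¹/dictionary operations stay below a
fixed multiple (64, chosen once from the per-step accounting, with the
measured maximum around 5) of `m + occ`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` (`--min-length`) | — | minimum reported match length, in symbols; the only knob a user must choose. Smaller `L` reports more, shorter matches |
| `d` (`--balance-d`) | 2 | balancing parameter; interval count ≤ `k + ceil(k/(d-1))`, scan ≤ `2d - 1` intervals |
| `variant` | `run_scan` | mismatch jumps by `ND`/`PD` walk (`run_scan`, matches the per-run amortization) or by rank-select binary search |
| `dict_mode` | `hashed` | `hashed`: expected O(1) dictionary; `ordered`: deterministic sorted-vector dictionary (logarithmic-class, insertion by splice — adequate at desk scale, standing in for a deterministic dictionary such as an exponential search tree) |
| `mode` (CLI) | `ms` | `ms` consumes matching statistics computed from the uncompressed oracle structures; `direct` reseeds by backward search, O(mL + occ), no matching statistics needed |

Matching statistics themselves are computed by an oracle routine
(`compute_ms_oracle`) over the uncompressed structures, with the witness
fixed deterministically to the smallest qualifying suffix-array row — any
witness is correct, a fixed one makes runs reproducible. Computing matching
statistics inside O(r) space is an open problem and out of scope; the direct
mode exists precisely so the compressed index alone suffices.

## The synthetic panel generator

`simulate_panel` emulates the data the index targets: `n_haplotypes` copies
of one random founder, each point-mutated independently at `mutation_rate`
per site (default alphabet `a/c/g/t`), concatenated with per-sequence
sentinels; one extra mutated copy is the held-out query. Low rates give the
highly repetitive, run-compressible texts of interest (the suite checks that
`r/n` falls as the rate drops); rate 0 gives identical copies, rate 1 on a
binary alphabet gives complements. It deliberately does *not* model
recombination, indels, structural variation, coalescent genealogies or base
composition — so passing tests demonstrate correctness of the combinatorics
on repetitive collections, not realism of any population-genetic inference.
Real genomes also carry ambiguity codes: the text builder ranks any character
it sees, while pattern symbols absent from the text's alphabet are mapped to
a non-matching rank (they break matches, as they should, and are logged by
the CLI).

## Numerical and degenerate-input choices

* Everything user-visible is 1-based inclusive; all values are integers, so
  there are no tolerances anywhere — every comparison in the suite is exact.
* Windows exist only for `f` in `[1, m - L + 1]`; `L > m` returns an empty
  result, `L < 1` is an error. The final flush plays the role of an `f = 0`
  iteration without special-casing the emit path.
* Texts of a single sentinel (`n = 1`), single-interval structures, empty
  patterns, and patterns sharing no symbol with the text all take the normal
  code paths (verified by tests).
* The middle row of a restarted interval is pinned to the seed row; the
  `seed_window` restart hands over its middle row because that is the row
  carrying both φ and φ⁻¹ interval indices. `interval_of` (binary search
  over interval starts) is used only at construction/augmentation time,
  never on the query's per-step path.
* Emission order is discovery order; the CLI sorts by `(p_start, t_start)`
  for canonical diffs, and tests compare as sets.
* Serialization is a versioned JSON container of named integer arrays:
  platform-independent, diffable, and loadable only by a matching version.

## Problem sizes in the shipped suites

The test and acceptance suites run entirely on generated data: panels up to
about 20 haplotypes of up to 400 sites (`n` up to ~8,000, `r/n` down to
~0.07), patterns up to ~400 symbols, thresholds `L` in {2, 4, 8, 16, 32},
200 oracle-equivalence instances plus smaller batches per property. These
sizes keep the brute-force oracles (O(nm) per instance) comfortable while
exercising every code path; nothing in the algorithms is specific to them.

## Known limitations

* Construction is O(n log n) time and O(n) transient space — the compressed
  object is the *output* of construction, not its working set. Run-length
  scale construction is out of scope.
* The O(m + occ) bound is expected time (hashed dictionary) and assumes the
  matching statistics are given; the direct mode costs O(mL) extra.
* R-level constant factors are what they are: this is a reference
  implementation for method development and verification, not a
  chromosome-scale production indexer.
* The φ and φ⁻¹ structures are separate; a merged structure answering both
  directions from one interval index would halve the samples but is not
  implemented.
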