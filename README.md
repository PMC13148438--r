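# lemindex

Long locally maximal exact match (LEM) queries on a run-length compressed
BWT index, in R.

## The problem

Pangenomes and biobank-scale haplotype panels are enormous but extremely
repetitive: the Burrows–Wheeler transform (BWT) of such a collection has far
fewer equal-character runs (`r`) than symbols (`n`), and indexes whose size is
O(r) rather than O(n) make them queryable. The classical match type reported
by compressed indexes is the **MEM** — a match between a query pattern `P`
(|P| = m) and a text `T` (|T| = n) that cannot be extended *in the pattern*.
MEMs miss biologically informative similarity: a haplotype closely related to
the query everywhere, but nowhere maximally similar, can share no MEM with it.

A **locally maximal exact match (LEM)** `P[i, j] = T[i', j']` is a match that
cannot be extended *simultaneously* in the pattern and the text:

```
(i = 1  or  i' = 1  or  P[i-1] != T[i'-1])   and
(j = m  or  j' = n  or  P[j+1] != T[j'+1])
```

Equivalently, LEMs are the maximal runs of agreement along pattern-vs-text
diagonals; MEMs are a subset. A **long LEM** is a LEM of length at least a
threshold ℒ. This package implements an index and query that report *all*
long LEMs of a pattern in O(m + occ) expected time, where `occ` is the number
of matches reported, using only run-length compressed structures.

## What the index stores

The index couples three *move data structures* — piecewise-shift
representations of permutations of `[1, n]`, balanced so each query is a
constant-time table step plus a bounded scan — with per-interval samples:

* `F(I_LF)` for the LF mapping (input intervals lie within BWT runs);
* `F(I_phi, PLCP)` for φ (the suffix immediately above in suffix-array order),
  over the run-top suffix starts, augmented with permuted-LCP samples `LCP+`
  so that `PLCP[i] = LCP+[x] - (i - p_x)` inside interval `x`;
* `F(I_phi_inv, PLCP)` for φ⁻¹ over the run-bottom suffix starts, augmented
  with `LCP-` samples giving `PLCP[phi_inv(i)]` — the LCP directly *below* a
  row — in constant time;
* a rank-select structure over `Lfirst` (the BWT symbol of each LF interval),
  run-jump arrays `ND`/`PD`, and suffix-array samples at LF-interval
  boundaries with their φ/φ⁻¹ interval indices.

No plain suffix array survives construction: everything the query touches is
O(#intervals) = O(r) words.

The query slides a length-ℒ window right-to-left over the pattern,
maintaining the *balanced sa_lcp-interval* of the current window — a 13-tuple
tracking the top, middle and bottom rows of the window's suffix-array
interval together with their SA values and move-structure interval indices —
plus a diagonal-keyed dictionary mapping each live text suffix to the end of
its longest match. Each advancement emits the matches whose left end dies at
this window (their BWT symbol differs from the next pattern symbol), extends
the interval by one symbol via LF steps, and re-expands it with φ/φ⁻¹ steps
while the boundary LCP stays at least ℒ. Matching statistics (or, in the
direct mode, an O(ℒ) backward search per reseed) restart the interval when it
empties.

## Worked example

```r
library(lemindex)

tx  <- text_from_strings("abaab")          # text T = "abaab$"
idx <- build_index(tx)                     # run-length compressed index
pat <- map_pattern(tx, "aab")              # pattern P = "aab"
ms  <- augment_ms(idx, compute_ms_oracle(build_suffix_structures(tx), pat))

long_lem_query(idx, pat, ms, L = 2)
#>   p_start t_start length
#> 1       1       3      3
#> 2       2       1      2
```

The two rows say: `P[1,3] = "aab"` matches `T[3,5]` (length 3, maximal on its
diagonal), and `P[2,3] = "ab"` matches `T[1,2]` (length 2, blocked on the
left by the text edge). The second occurrence of `"ab"` at `T[4,5]` is *not*
reported: it extends simultaneously on the left (`P[1] = T[3] = 'a'`), so it
is not locally maximal. `long_lem_query_direct(idx, pat, L = 2)` returns the
same set without using matching statistics.

The same pipeline is scriptable from a shell:

```sh
exec/lemindex simulate --haplotypes 10 --length 400 --rate 0.002 --seed 1 \
    --out panel.fa --query query.fa
exec/lemindex build   --input panel.fa --output panel.idx.json
exec/lemindex longlem --index panel.idx.json --pattern query.fa \
    --min-length 16 --out matches.tsv
exec/lemindex oracle  --text panel.fa --pattern query.fa --min-length 16
```

`matches.tsv` has 1-based inclusive columns `pattern_id, p_start, t_start,
t_seq_id, t_offset, length`; the `oracle` subcommand emits the brute-force
answer in the same dialect for diffing.

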