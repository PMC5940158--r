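---
title: "Methods: pointer words, reduction algebra, and nesting metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pointer words, reduction algebra, and nesting metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblekit)
```

## The rearrangement model

A macronuclear (MAC) chromosome is assembled from `k` germline segments
(MDSs) that appear along the micronuclear (MIC) genome in some signed order —
the *arrangement*, written `M2 M3 -M8 -M7 -M1 -M4 M5 M6` where a minus sign
marks an inverted segment. An arrangement is *nonscrambled* exactly when it is
`M1 ... Mk` all forward or `-Mk ... -M1` all inverted; anything else is
scrambled.

Consecutive MDSs of the product share junction *pointers* numbered
`1 .. k-1`: pointer `i` sits at the junction between `Mi` and `Mi+1`. Reading
along the MIC locus, a forward `Mi` contributes its pointers in the order
`(i-1, i)` and an inverted `Mi` in the order `(i, i-1)`; pointers `0` and `k`
do not exist (terminal MDSs contribute one pointer each). The result is a
*double occurrence word* (DOW): every label occurs exactly twice.

```{r}
format(pointer_word(parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6")))
```

Two modelling consequences worth stating as limitations:

- The pointer word is blind to the orientation of terminal MDSs (they emit a
  single pointer, so no relative orientation is recorded at the ends), and for
  `k = 2` the words of `M1 M2` and `M2 M1` are indistinguishable (`11`).
  Scrambledness is therefore always decided on the arrangement itself
  (`is_scrambled()`), never on the word.
- The word is a complexity measure of the map, not a mechanistic model of the
  descrambling pathway.

## Trivial pairs and conventional IESs

An IES flanked by consecutive, co-oriented MDSs (`Mi Mi+1` both forward, or
`Mi+1 Mi` read off two inverted segments, i.e. descending inverted) is
*conventional*; it shows up in the word as an adjacent identical pair
(`...ii...`). `strip_trivial_pairs()` removes such pairs with a stack pass so
that removals can cascade, and `renumber_by_rank()` maps the surviving labels
onto `1..m` preserving rank. Coordinate-level `ies_intervals()` flags exactly
the same junctions as conventional, and the test suite checks that the two
views agree.

## Repeat/return reduction

A *repeat word* is a pair of disjoint contiguous occurrences of the same
factor `u` (with `|u| >= 2`); a *return word* pairs `u` with its reversal. A
hit is *maximal* when it cannot be extended by one symbol on either side.
`reduce_dow()` deletes one hit at a time and records a full trace.

Removal order can matter, so two strategies exist:

- **greedy** (default): first strip any trivial pair *not covered by* a
  maximal pattern hit, then choose the longest maximal hit, breaking ties by
  the *innermost* hit (smallest total extent `start_b + |u| - start_a`), then
  leftmost. Stripping an adjacent pair never destroys reducibility — the only
  pattern hit that can involve one is an adjacent return word `v i | i
  rev(v)`, which survives stripping as `v·rev(v)` — whereas removing a
  pattern hit *across* a free pair can (in `561143564232` the pair `11` must
  go before the repeat `56·56`, or the longer repeat `564·564` is never
  exposed). Covered pairs are left to the pattern removal, which keeps the
  published traces: `3443` is removed as one return word, and the innermost
  tie-break makes the published step-by-step intermediates come out exactly.
- **exhaustive**: depth-first search over *every* hit — repeat/return of any
  maximality, plus trivial pairs — with memoization on canonicalized words.
  It returns a trace to the empty word whenever some order reaches it,
  otherwise to a minimal-length residual, so this strategy is the arbiter of
  "reducible". Restricting the branching to maximal hits would be
  incomplete. The memo key is the first-occurrence canonical form, so
  permuted labels share one entry. Beyond `max_labels_exhaustive` (default
  40) labels the function falls back to greedy with a warning — the search is
  exponential in the worst case and 40 labels is far above every published
  locus (max observed: 13 pointers after stripping).

Greedy remains a one-step-lookahead heuristic: on `525146323146` it dead-ends
while the exhaustive search reaches the empty word. Such words are rare
(about 0.1% of random 6-label words) but they exist, so reducibility claims
should always come from the exhaustive strategy; greedy supplies the
deterministic traces and residuals that are reported.

```{r}
reduce_dow(parse_dow("121342566534"))
```

## Tangled cords

`tangled_cord(n)` builds the family `1212, 121323, 12132434, ...` by inserting
each new label after the penultimate and last positions. `TC(1) = 1212`
reduces; `TC(n)` for `n >= 2` admits no repeat/return hit at all.
`contains_tangled_cord()` deletes label subsets (smallest deletions first, so
the largest embedded cord is found) and compares canonical forms, optionally
up to rotation (`cyclic = TRUE`) and reversal. Subset enumeration is capped at
20 labels; words that large should be reduced first.

## Nesting metrics

Given MDS coordinate records, containment is *strict* (the MDS must be a
proper subset of the IES interval). Strictness is what guarantees the IDI
recursion terminates: a contained interval is strictly shorter, so the chain
of nested IESs is finite even for adversarial input.

- **EI** of a contig: the maximum, over its MDSs, of the number of distinct
  foreign contigs having an IES that strictly contains that MDS.
- **IDI** of a contig: 0 if no foreign MDS lies strictly inside any of its
  IESs; otherwise `1 + max` over such foreign contigs of the IDI computed on
  the material inside that IES. Mutually interleaved partners contribute depth
  1 to each other and the strict-containment argument stops the recursion.
- **classify_pair(a, b)**: `a` is *embedded* in `b` when *all* of `a`'s MDSs
  lie within a *single* IES of `b`; the pair is *interleaved* when each
  partner has at least one MDS inside an IES of the other (the mutual
  definition). A contig spanning two different IESs of its partner is
  therefore interleaved, not embedded.
- **terminal_overlap_filter()**: contigs of different MAC products whose MDSs
  overlap by more than `overlap_bp` (default 20 bp, comfortably above pointer
  scale) are excluded pairwise; `nesting_report()` keeps their rows with `NA`
  metrics and `excluded = TRUE` rather than dropping them silently.

Cohort statistics use base R: a 2x2 chi-square (no continuity correction) of
scrambled status against `IDI >= 1`, and an exact Spearman correlation of the
scrambled proportion across IDI classes. Degenerate tables (an empty margin,
or fewer than three distinct classes) are flagged `*_degenerate = TRUE` with
`NA` statistics instead of fabricating zeros. Note that the exact two-sided
p-value for `rho = 1` at `n = 4` is 0.083; a perfect rank correlation over
four classes cannot reach two-sided 0.05 by itself.

## The synthetic generator

`generate_architectures(sim_config(...))` is seeded once (`seed`, with RNG
kind pinned to Mersenne-Twister / Inversion / Rejection so output is stable
across R versions) and plants known structure:

| parameter | default | rationale |
|---|---|---|
| `n_mic_contigs`, `loci_per_contig` | 10, 3 | desk-scale cohorts in seconds |
| `nesting_depth_probs` | 0:.50 1:.30 2:.12 3:.05 4:.03 | skewed like observed nesting; depth 4 is the deepest reported |
| `fraction_interleaved` | 0.15 | minority pattern, as observed |
| `scramble_mix` | nonscrambled .70, odd-even .10, inverted odd-even .08, tangled cord .06, random permutation .06 | majority nonscrambled; named patterns kept frequent enough to appear in small cohorts |
| `tc_n_range` | 2–4 | irreducible cords of testable size |
| `mds_count_range` | 3–15 | covers the published examples |
| `mds_length_range`, `ies_length_range` | 60–300, 20–150 bp | orders of magnitude of real MDS/IES lengths |
| `host_gap_max` | Inf | set finite to force an infeasibility error instead of auto-growing host IESs |

Nested children are placed strictly inside a host IES which is auto-grown to
the child's width plus padding; `host_gap_max` bounds that growth and turns an
impossible request into an explicit error. Interleaved pairs are laid out as
`a1 b1 a2.. b2..`, which yields IDI = EI = 1 and class `interleaved_only` for
both partners. The truth table records arrangement, pattern, `tc_n`, IDI, EI,
relationship class, and scrambledness per MAC contig, and the test suite
recovers all of it from coordinates alone on 200+ contigs.

The generator does **not** emulate sequence content, pointer sequences,
chromosome copy number, alternative MDS usage, or measurement noise — it
produces clean coordinate architectures whose combinatorial truth is known.

## Problem sizes

Everything here is desk scale: pointer words up to tens of labels, exhaustive
reduction on up to 40 labels (tested exhaustively against a full-enumeration
oracle on all random DOWs with <= 6 labels), nesting reports on hundreds of
contigs in seconds, and SVG chord diagrams that are byte-identical across
runs.
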