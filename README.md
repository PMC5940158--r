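# scramblekit

Tools for analysing germline-to-somatic genome rearrangement maps of ciliates
such as *Oxytricha trifallax*.

In ciliates, each somatic (MAC) nanochromosome is assembled during development
from germline (MIC) segments called MDSs (macronuclear destined sequences),
separated by IESs (internally eliminated sequences) that are excised. Adjacent
MDSs share short repeats — *pointers* — that label the recombination
junctions. Reading the pointer occurrences along the germline yields a
*double occurrence word* (DOW): every pointer appears exactly twice. The
combinatorial structure of that word — how far it can be simplified by
removing *repeat words* (u ... u) and *return words* (u ... reverse(u)), and
whether it hides an irreducible *tangled cord* (1212, 121323, 12132434, ...)
— measures how scrambled the locus is. Independently, loci of different MAC
chromosomes can be *nested* (one gene inside another's IES) or *interleaved*
(MDSs alternating); scramblekit quantifies this with the insertion depth index
(IDI) and the embedding index (EI).

The package provides:

- **Arrangement model** — parse signed MDS arrangement notation
  (`"M2 M3 -M8 -M7 -M1 -M4 M5 M6"`), derive pointer words, detect scrambling,
  and lay out IES intervals from coordinate annotations.
- **DOW algebra** — trivial-pair stripping (conventional IESs), rank
  renumbering, maximal repeat/return word detection, greedy and exhaustive
  reduction with full step traces, tangled-cord generation and detection, and
  DOW isomorphism.
- **Nesting metrics** — IDI, EI, per-pair embedded/interleaved classification,
  a terminal-overlap exclusion filter, per-cohort summary tables, and
  chi-square / Spearman enrichment statistics.
- **Chord diagrams** — circular layouts with crossing counts, a ggplot2
  `autoplot()` method, and byte-deterministic SVG output.
- **Annotation IO** — a configurable GFF dialect reader that skips corrupt
  lines with recorded reasons, plus TSV report/trace writers.
- **Synthetic data** — a single-seed generator planting Russian-doll chains,
  interleaved pairs, and known scramble patterns with a ground-truth table.
- **CLI** — `inst/scripts/scramblekit` with `dow`, `reduce`, `tangled`,
  `nesting`, `classify`, `chord`, `simulate`, and `summarize` subcommands.

All user-facing functions take a data frame first where applicable and return
tibbles; result objects have broom-style `tidy()` / `glance()` methods.

## Worked example

```r
library(scramblekit)

map <- parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6")
is_scrambled(map)
#> [1] TRUE

w <- pointer_word(map)
format(w)
#> [1] "12237761434556"

stripped <- strip_trivial_pairs(w)   # conventional IESs drop out
stripped$removed
#> [1] 3
format(renumber_by_rank(stripped$word))
#> [1] "12413234"

scrambled_pointer_count(stripped$word)
#> [1] 4
contains_tangled_cord(renumber_by_rank(stripped$word))
#> [1] 2

reduce_dow(parse_dow("12341243"))
#> <reduction_trace> 12341243 -> ε (2 steps, greedy)
#> # A tibble: 2 x 7
#>    step kind   u     start_a start_b word_before word_after
#>   <int> <chr>  <chr>   <int>   <int> <chr>       <chr>
#> 1     1 repeat 12          1       5 12341243    "3443"
#> 2     2 return 34          1       3 3443        ""
```

Nesting metrics on coordinate annotations:

```r
rec <- nested_demo_records()   # three loci nested like Russian dolls
nesting_report(rec)[, c("mac_contig_id", "idi", "ei", "relationship_class")]
#> # A tibble: 3 x 4
#>   mac_contig_id   idi    ei relationship_class
#>   <chr>         <int> <int> <chr>
#> 1 blue              1     1 embedded_only
#> 2 orange            0     2 embedded_only
#> 3 red               2     0 none
```

Chord diagram of a word:

```r
lay <- chord_layout(parse_dow("121323"))
chord_crossings(lay)
render_svg(lay, "tangled.svg")      # byte-deterministic output
ggplot2::autoplot(lay)
```

Simulate a cohort and analyse it end to end:

```r
sim <- generate_architectures(sim_config(seed = 1, n_mic_contigs = 10))
reports <- nesting_report(sim$records)
summarize_nesting(reports)
enrichment_stats(reports)
```

## GFF dialect

`read_mds_gff()` expects GFF3-like lines whose attribute column carries the
MAC contig, MDS index, and orientation. The defaults are

| setting           | default                 |
|-------------------|-------------------------|
| `feature_types`   | `MDS`, `mds`            |
| `mac_attr`        | `mac_contig`            |
| `index_attr`      | `mds_index`             |
| `orientation_attr`| `orientation`           |

If the orientation attribute is absent, the strand column is used (`-` means
inverted). Other keys can be supplied with `gff_dialect()` or a YAML file via
`read_dialect_yaml()`. Corrupt lines are skipped, not fatal; each skip is
recorded with a reason (`field_count`, `malformed_coordinates`,
`missing_attribute`, `bad_orientation`) in the `skipped` tibble.

## Command line

```sh
inst/scripts/scramblekit dow "M1 -M2 -M3"          # 1212
inst/scripts/scramblekit reduce 12341243 --trace
inst/scripts/scramblekit tangled 12413234           # 2
inst/scripts/scramblekit simulate --seed 7 -o sim.gff --truth truth.tsv
inst/scripts/scramblekit nesting sim.gff --summary
inst/scripts/scramblekit chord 12132434 -o cord.svg
```

Words are accepted as digit strings (labels 1–9) or comma-separated integers.
Exit codes: 0 success, 1 runtime failure, 2 usage error.

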