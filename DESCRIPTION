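Package: scramblekit
Title: Double-Occurrence-Word Analysis of Scrambled Ciliate Genome Rearrangement Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing germline-to-somatic genome rearrangement maps of
    ciliates such as Oxytricha trifallax. Parses signed MDS arrangement notation and
    MDS annotation tables (a GFF dialect), derives pointer double-occurrence words,
    applies the repeat/return reduction algebra, detects tangled-cord patterns,
    computes the nesting metrics IDI (insertion depth index) and EI (embedding
    index) with embedded/interleaved classification and enrichment statistics,
    renders chord diagrams as deterministic SVG, and ships a seeded synthetic
    architecture generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
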