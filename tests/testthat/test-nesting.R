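test_that("IES intervals abut their flanking MDSs and flag conventional junctions", {
  rec <- tibble::tibble(
    mic_contig_id = "m", mac_contig_id = "a",
    mds_index = 1:3, mic_start = c(1L, 21L, 41L), mic_end = c(10L, 30L, 50L),
    orientation = "forward"
  )
  ies <- ies_intervals(rec)
  expect_identical(ies$start, c(11L, 31L))
  expect_identical(ies$end, c(20L, 40L))
  expect_true(all(ies$conventional))
  expect_identical(nrow(ies), nrow(rec) - 1L)

  # the 8-MDS scrambled locus: 7 intervals, 3 conventional
  map <- parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6")
  ies8 <- ies_intervals(records_from_arrangement(map))
  expect_identical(nrow(ies8), 7L)
  expect_identical(sum(ies8$conventional), 3L)
  # conventional junctions are exactly the trivial pairs of the pointer word
  expect_identical(
    sum(ies8$conventional),
    strip_trivial_pairs(pointer_word(map))$removed
  )

  overlapping <- rec
  overlapping$mic_start[2] <- 5L
  expect_error(ies_intervals(overlapping), "overlapping")
})

test_that("descending inverted runs are conventional, co-oriented misorders are not", {
  ies <- ies_intervals(
    records_from_arrangement(parse_arrangement("-M3 -M2 -M1"))
  )
  expect_true(all(ies$conventional))
  ies2 <- ies_intervals(
    records_from_arrangement(parse_arrangement("M3 M2 M1"))
  )
  expect_false(any(ies2$conventional))
})

test_that("the three-layer fixture reproduces the canonical IDI and EI values", {
  for (ids in list(
    c("red", "blue", "orange"),
    c("Contig6331.0", "Contig9583.0", "Contig6683.0")
  )) {
    rec <- nested_demo_records(ids = ids)
    expect_identical(idi_of_contig(ids[1], rec), 2L)
    expect_identical(idi_of_contig(ids[2], rec), 1L)
    expect_identical(idi_of_contig(ids[3], rec), 0L)
    expect_identical(ei_of_contig(ids[1], rec), 0L)
    expect_identical(ei_of_contig(ids[2], rec), 1L)
    expect_identical(ei_of_contig(ids[3], rec), 2L)
    expect_identical(classify_pair(ids[2], ids[1], rec), "a_embedded_in_b")
    expect_identical(classify_pair(ids[3], ids[2], rec), "a_embedded_in_b")
    expect_identical(classify_pair(ids[1], ids[2], rec), "b_embedded_in_a")
    expect_identical(relationship_class(ids[3], rec), "embedded_only")
    expect_identical(relationship_class(ids[1], rec), "none")
  }
})

test_that("a Russian-doll chain of depth d has outermost IDI and innermost EI d - 1", {
  sim <- generate_architectures(sim_config(
    seed = 99L, n_mic_contigs = 1L, loci_per_contig = 1L,
    nesting_depth_probs = c("4" = 1), fraction_interleaved = 0,
    scramble_mix = c(
      nonscrambled = 1, odd_even = 0, inverted_odd_even = 0,
      tangled_cord = 0, random_permutation = 0
    )
  ))
  expect_identical(nrow(sim$truth), 5L) # 5 nested genes
  rep <- nesting_report(sim$records)
  expect_identical(max(rep$idi), 4L)
  expect_identical(max(rep$ei), 4L)
  outer_id <- sim$truth$mac_contig_id[sim$truth$ei == 0]
  inner_id <- sim$truth$mac_contig_id[sim$truth$ei == 4]
  expect_identical(rep$idi[rep$mac_contig_id == outer_id], 4L)
  expect_identical(rep$ei[rep$mac_contig_id == inner_id], 4L)
})

test_that("mutually interleaved loci classify and terminate the IDI recursion", {
  # a1 b1 a2 a3 b2 b3 on one MIC contig
  mk <- function(mac, starts, idx = seq_along(starts)) {
    tibble::tibble(
      mic_contig_id = "m", mac_contig_id = mac, mds_index = idx,
      mic_start = starts, mic_end = starts + 9L, orientation = "forward"
    )
  }
  layout <- dplyr::bind_rows(
    mk("a", c(1L, 101L, 201L)),
    mk("b", c(51L, 301L, 401L))
  )
  expect_identical(classify_pair("a", "b", layout), "interleaved")
  expect_identical(relationship_class("a", layout), "interleaved_only")
  expect_identical(relationship_class("b", layout), "interleaved_only")
  expect_identical(idi_of_contig("a", layout), 1L)
  expect_identical(idi_of_contig("b", layout), 1L)
  expect_identical(ei_of_contig("a", layout), 1L)
  expect_identical(ei_of_contig("b", layout), 1L)
})

test_that("a contig with embedded and interleaved partners classifies as both", {
  mk <- function(mac, starts) {
    tibble::tibble(
      mic_contig_id = "m", mac_contig_id = mac,
      mds_index = seq_along(starts),
      mic_start = starts, mic_end = starts + 9L, orientation = "forward"
    )
  }
  # t interleaves with b (t1 b1 t2 b2) and is embedded in host's huge IES
  layout <- dplyr::bind_rows(
    mk("host", c(1L, 1001L)),
    mk("t", c(101L, 301L)),
    mk("b", c(201L, 401L))
  )
  expect_identical(relationship_class("t", layout), "both")
  expect_identical(relationship_class("host", layout), "none")
})

test_that("disjoint loci and one-sided straddles do not interleave", {
  mk <- function(mac, starts) {
    tibble::tibble(
      mic_contig_id = "m", mac_contig_id = mac,
      mds_index = seq_along(starts),
      mic_start = starts, mic_end = starts + 9L, orientation = "forward"
    )
  }
  disjoint <- dplyr::bind_rows(mk("a", c(1L, 51L)), mk("b", c(201L, 251L)))
  expect_identical(classify_pair("a", "b", disjoint), "none")
  # a contig spanning two different IESs of its partner is interleaved with
  # it, not embedded (embedding demands a single IES)
  two_ies <- dplyr::bind_rows(
    mk("a", c(1L, 101L, 201L)),
    mk("b", c(51L, 151L))
  )
  expect_identical(classify_pair("b", "a", two_ies), "interleaved")
})

test_that("removing a contig never increases another contig's EI", {
  set.seed(77)
  sim <- generate_architectures(sim_config(seed = 77L, n_mic_contigs = 3L))
  layouts <- dplyr::group_split(sim$records, mic_contig_id)
  for (layout in layouts[1:2]) {
    macs <- unique(layout$mac_contig_id)
    if (length(macs) < 2) next
    before <- vapply(macs, ei_of_contig, integer(1), layout = layout)
    drop <- macs[[1]]
    kept <- dplyr::filter(layout, mac_contig_id != drop)
    for (m in setdiff(macs, drop)) {
      expect_lte(ei_of_contig(m, kept), before[[m]])
    }
  }
})

test_that("the terminal-overlap filter excludes both contigs past the threshold", {
  mk <- function(mac, start, end) {
    tibble::tibble(
      mic_contig_id = "m", mac_contig_id = mac, mds_index = 1L,
      mic_start = start, mic_end = end, orientation = "forward"
    )
  }
  big <- dplyr::bind_rows(mk("a", 1L, 200L), mk("b", 101L, 300L)) # 100 bp
  expect_identical(terminal_overlap_filter(big), c("a", "b"))
  abutting <- dplyr::bind_rows(mk("a", 1L, 100L), mk("b", 101L, 200L))
  expect_identical(terminal_overlap_filter(abutting), character(0))
  pointer_scale <- dplyr::bind_rows(mk("a", 1L, 100L), mk("b", 96L, 200L)) # 5 bp
  expect_identical(terminal_overlap_filter(pointer_scale), character(0))
  expect_identical(
    terminal_overlap_filter(pointer_scale, overlap_bp = 2L), c("a", "b")
  )
  rep <- suppressWarnings(nesting_report(big))
  expect_true(all(rep$excluded))
  expect_true(all(is.na(rep$idi)))
})

test_that("Spearman correlation over IDI classes flags degenerate inputs", {
  out <- idi_scrambled_correlation(1:4, c(62.3, 74.4, 90.9, 100))
  expect_identical(out$rho, 1)
  expect_false(out$degenerate)
  flat <- idi_scrambled_correlation(1:4, rep(22.2, 4))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$rho))
})

test_that("chi-square enrichment detects planted scrambling enrichment", {
  set.seed(55)
  hits <- 0L
  n_sim <- 40L
  for (i in seq_len(n_sim)) {
    n <- 400L
    nested <- rep(c(TRUE, FALSE), c(100L, 300L))
    scrambled <- ifelse(nested, runif(n) < 0.6, runif(n) < 0.15)
    reports <- tibble::tibble(
      mac_contig_id = as.character(seq_len(n)),
      idi = ifelse(nested, 1L + (seq_len(n) %% 3L), 0L),
      ei = 0L, relationship_class = "none",
      scrambled = scrambled, mds_count = 5L,
      complete = TRUE, excluded = FALSE
    )
    st <- enrichment_stats(reports)
    expect_false(st$chi2_degenerate)
    if (st$chi2_p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("enrichment statistics flag degenerate cohorts instead of zeroing them", {
  reports <- tibble::tibble(
    mac_contig_id = c("a", "b"), idi = c(0L, 0L), ei = 0L,
    relationship_class = "none", scrambled = c(TRUE, FALSE),
    mds_count = 3L, complete = TRUE, excluded = FALSE
  )
  st <- enrichment_stats(reports)
  expect_true(st$chi2_degenerate)
  expect_true(st$spearman_degenerate)
  expect_true(is.na(st$chi2_stat))
})

test_that("summary tables recover known class counts and handle empty input", {
  rec <- nested_demo_records()
  tabs <- summarize_nesting(nesting_report(rec))
  idi_tab <- dplyr::filter(tabs$by_index, metric == "IDI")
  expect_identical(idi_tab$class, c(0L, 1L, 2L))
  expect_identical(idi_tab$n_contigs, c(1L, 1L, 1L))
  rel <- tabs$relationships
  expect_identical(
    rel$n_contigs[rel$category == "embedded_only"], 2L
  )
  expect_identical(rel$n_contigs[rel$category == "interleaved_only"], 0L)

  empty <- summarize_nesting(nesting_report(tibble::tibble(
    mic_contig_id = character(), mac_contig_id = character(),
    mds_index = integer(), mic_start = integer(), mic_end = integer(),
    orientation = character()
  )))
  expect_identical(nrow(empty$by_index), 0L)
  expect_true(all(empty$relationships$n_contigs == 0L))
})
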