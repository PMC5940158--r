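#' Simulation configuration for synthetic MIC/MAC architectures
#'
#' Defines the study conditions the generator emulates: germline (MIC)
#' contigs carrying nanochromosome precursor loci that are nested to a
#' planted depth (Russian-doll chains), sometimes mutually interleaved, with
#' a mix of scrambling patterns (nonscrambled, odd-even repeat/return,
#' tangled cords, random signed permutations). Lengths exist only to create
#' realistic coordinates; no sequence is simulated.
#'
#' @param seed Integer seed driving one pseudo-random stream
#'   (Mersenne-Twister; fixed explicitly, not the platform default).
#' @param n_mic_contigs Number of MIC contigs.
#' @param loci_per_contig Locus slots per MIC contig (a slot becomes either a
#'   doll chain or an interleaved pair).
#' @param nesting_depth_probs Named probabilities over planted chain depths
#'   (outermost IDI); names are the depth values.
#' @param fraction_interleaved Probability that a slot is an interleaved pair
#'   rather than a chain.
#' @param scramble_mix Named proportions over arrangement patterns
#'   `nonscrambled`, `odd_even`, `inverted_odd_even`, `tangled_cord`,
#'   `random_permutation`; must sum to 1.
#' @param tc_n_range Range of tangled-cord sizes `n` for tangled loci.
#' @param mds_count_range Range of MDS counts per locus (>= 3).
#' @param mds_length_range,ies_length_range Base-pair ranges for MDS and IES
#'   lengths (positive).
#' @param host_gap_max Capacity limit for a host IES that receives a nested
#'   child locus; configurations whose children exceed it are rejected with
#'   an error naming the constraint.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_mic_contigs = 10L,
                       loci_per_contig = 3L,
                       nesting_depth_probs = c(
                         "0" = 0.50, "1" = 0.30, "2" = 0.12,
                         "3" = 0.05, "4" = 0.03
                       ),
                       fraction_interleaved = 0.15,
                       scramble_mix = c(
                         nonscrambled = 0.70, odd_even = 0.10,
                         inverted_odd_even = 0.08, tangled_cord = 0.06,
                         random_permutation = 0.06
                       ),
                       tc_n_range = c(2L, 4L),
                       mds_count_range = c(3L, 15L),
                       mds_length_range = c(60L, 300L),
                       ies_length_range = c(20L, 150L),
                       host_gap_max = Inf) {
  if (abs(sum(scramble_mix) - 1) > 1e-8) {
    stop("scramble_mix proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(nesting_depth_probs) - 1) > 1e-8) {
    stop("nesting_depth_probs must sum to 1", call. = FALSE)
  }
  if (any(c(mds_length_range, ies_length_range) <= 0)) {
    stop("MDS and IES lengths must be positive", call. = FALSE)
  }
  if (mds_count_range[1L] < 3L) {
    stop("mds_count_range minimum is 3", call. = FALSE)
  }
  known <- c(
    "nonscrambled", "odd_even", "inverted_odd_even", "tangled_cord",
    "random_permutation"
  )
  if (!setequal(names(scramble_mix), known)) {
    stop("scramble_mix must name exactly: ", paste(known, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_mic_contigs = as.integer(n_mic_contigs),
      loci_per_contig = as.integer(loci_per_contig),
      nesting_depth_probs = nesting_depth_probs,
      fraction_interleaved = fraction_interleaved,
      scramble_mix = scramble_mix,
      tc_n_range = as.integer(tc_n_range),
      mds_count_range = as.integer(mds_count_range),
      mds_length_range = as.integer(mds_length_range),
      ies_length_range = as.integer(ies_length_range),
      host_gap_max = host_gap_max
    ),
    class = "sim_config"
  )
}

sample_range <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n) else sample(range[1L]:range[2L], n, replace = TRUE)
}

# Arrangement entries for one planted pattern.
make_arrangement_entries <- function(pattern, k, tc_n = NA_integer_) {
  switch(pattern,
    nonscrambled = tibble::tibble(
      mds_index = seq_len(k), orientation = "forward"
    ),
    odd_even = tibble::tibble(
      mds_index = c(seq(1L, k, 2L), seq(2L, k, 2L)), orientation = "forward"
    ),
    inverted_odd_even = tibble::tibble(
      mds_index = c(seq(1L, k, 2L), rev(seq(2L, k, 2L))),
      orientation = rep(
        c("forward", "inverted"),
        c(length(seq(1L, k, 2L)), length(seq(2L, k, 2L)))
      )
    ),
    tangled_cord = tibble::tibble(
      mds_index = c(1L, 2:(tc_n + 2L)),
      orientation = c("forward", rep("inverted", tc_n + 1L))
    ),
    random_permutation = tibble::tibble(
      mds_index = sample(k),
      orientation = sample(c("forward", "inverted"), k, replace = TRUE)
    ),
    stop("unknown pattern: ", pattern, call. = FALSE)
  )
}

gen_locus <- function(cfg, mac_id) {
  pattern <- sample(names(cfg$scramble_mix), 1L, prob = cfg$scramble_mix)
  tc_n <- NA_integer_
  if (pattern == "tangled_cord") {
    tc_n <- sample_range(cfg$tc_n_range)
    k <- tc_n + 2L
  } else {
    k <- sample_range(cfg$mds_count_range)
  }
  entries <- make_arrangement_entries(pattern, k, tc_n)
  list(
    mac_id = mac_id, pattern = pattern, tc_n = tc_n, k = k,
    entries = entries,
    mds_lens = sample_range(cfg$mds_length_range, k),
    gaps = sample_range(cfg$ies_length_range, k - 1L)
  )
}

# Lay out one locus in relative coordinates (starting at 1), optionally
# hosting a pre-built child block inside one IES gap.
realize_locus <- function(locus, cfg, child = NULL, pad = 10L) {
  gaps <- locus$gaps
  host_gap <- NA_integer_
  if (!is.null(child)) {
    host_gap <- sample.int(length(gaps), 1L)
    need <- child$width + 2L * pad
    if (need > cfg$host_gap_max) {
      stop(
        "infeasible config: child locus block (", child$width,
        " bp + padding) exceeds host IES capacity (host_gap_max = ",
        cfg$host_gap_max, ")",
        call. = FALSE
      )
    }
    gaps[host_gap] <- need
  }
  k <- locus$k
  starts <- integer(k)
  ends <- integer(k)
  pos <- 1L
  child_offset <- NA_integer_
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + locus$mds_lens[i] - 1L
    pos <- ends[i] + 1L
    if (i < k) {
      if (!is.null(child) && i == host_gap) {
        child_offset <- pos + pad - 1L
      }
      pos <- pos + gaps[i]
    }
  }
  records <- tibble::tibble(
    mac_contig_id = locus$mac_id,
    mds_index = locus$entries$mds_index,
    orientation = locus$entries$orientation,
    mic_start = starts,
    mic_end = ends
  )
  if (!is.null(child)) {
    shifted <- dplyr::mutate(
      child$records,
      mic_start = .data$mic_start + child_offset,
      mic_end = .data$mic_end + child_offset
    )
    records <- dplyr::bind_rows(records, shifted)
  }
  list(records = records, width = pos - 1L)
}

locus_truth <- function(locus, idi, ei, class) {
  map <- new_arrangement_map(locus$mac_id, locus$entries)
  tibble::tibble(
    mac_contig_id = locus$mac_id,
    idi = idi, ei = ei, relationship_class = class,
    scrambled = is_scrambled(map),
    pattern = locus$pattern,
    tc_n = locus$tc_n,
    mds_count = locus$k,
    arrangement = format(map)
  )
}

# A Russian-doll chain: depth + 1 loci, each child wholly inside one IES of
# its parent. Level 0 is outermost.
gen_chain <- function(cfg, depth, id_prefix) {
  loci <- lapply(0:depth, function(lv) {
    gen_locus(cfg, sprintf("%s_L%d", id_prefix, lv))
  })
  block <- NULL
  for (lv in depth:0) {
    block <- realize_locus(loci[[lv + 1L]], cfg, child = block)
  }
  truth <- dplyr::bind_rows(lapply(0:depth, function(lv) {
    locus_truth(
      loci[[lv + 1L]],
      idi = depth - lv, ei = lv,
      class = if (lv == 0L) "none" else "embedded_only"
    )
  }))
  list(records = block$records, width = block$width, truth = truth)
}

# A mutually interleaved pair: MIC order a1 b1 a2..a_ka b2..b_kb, so each
# locus has at least one MDS inside an IES of the other.
gen_interleaved_pair <- function(cfg, id_prefix) {
  a <- gen_locus(cfg, paste0(id_prefix, "_A"))
  b <- gen_locus(cfg, paste0(id_prefix, "_B"))
  order_spec <- rbind( # (locus, slot) in MIC order

    c(1L, 1L), c(2L, 1L),
    cbind(1L, 2:a$k), cbind(2L, 2:b$k)
  )
  loci <- list(a, b)
  pos <- 1L
  rows <- list()
  for (r in seq_len(nrow(order_spec))) {
    which_locus <- order_spec[r, 1L]
    slot <- order_spec[r, 2L]
    loc <- loci[[which_locus]]
    len <- loc$mds_lens[slot]
    rows[[r]] <- tibble::tibble(
      mac_contig_id = loc$mac_id,
      mds_index = loc$entries$mds_index[slot],
      orientation = loc$entries$orientation[slot],
      mic_start = pos,
      mic_end = pos + len - 1L
    )
    pos <- pos + len
    if (r < nrow(order_spec)) {
      pos <- pos + sample_range(cfg$ies_length_range)
    }
  }
  truth <- dplyr::bind_rows(
    locus_truth(a, idi = 1L, ei = 1L, class = "interleaved_only"),
    locus_truth(b, idi = 1L, ei = 1L, class = "interleaved_only")
  )
  list(
    records = dplyr::bind_rows(rows), width = pos - 1L, truth = truth
  )
}

#' Generate a synthetic MIC/MAC architecture with ground truth
#'
#' Deterministic for a fixed seed: the same `sim_config` always yields
#' byte-identical annotation output. Planted properties hold by
#' construction: odd-even loci have pointer words that strip/reduce to the
#' empty word's complexity class, tangled-cord loci have pointer word
#' `TC(n)`, chain loci have the planted IDI/EI, and interleaved pairs are
#' mutually interleaved.
#'
#' @param config A [sim_config()].
#' @return A `sim_architecture`: list with `records` (MDS record tibble),
#'   `truth` (planted per-contig tibble: `mac_contig_id`, `idi`, `ei`,
#'   `relationship_class`, `scrambled`, `pattern`, `tc_n`, `mds_count`,
#'   `arrangement`) and `config`.
#' @export
generate_architectures <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed,
    kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection"
  )
  all_records <- list()
  all_truth <- list()
  depths <- as.integer(names(config$nesting_depth_probs))
  for (m in seq_len(config$n_mic_contigs)) {
    mic_id <- sprintf("MIC_%03d", m)
    pos <- 1L
    for (s in seq_len(config$loci_per_contig)) {
      prefix <- sprintf("MAC_%03d_%d", m, s)
      unit <- if (stats::runif(1L) < config$fraction_interleaved) {
        gen_interleaved_pair(config, prefix)
      } else {
        depth <- if (length(depths) == 1L) {
          depths
        } else {
          sample(depths, 1L, prob = config$nesting_depth_probs)
        }
        gen_chain(config, depth, prefix)
      }
      unit$records <- dplyr::mutate(
        unit$records,
        mic_contig_id = mic_id,
        mic_start = .data$mic_start + pos - 1L,
        mic_end = .data$mic_end + pos - 1L,
        .before = 1L
      )
      all_records[[length(all_records) + 1L]] <- unit$records
      all_truth[[length(all_truth) + 1L]] <- dplyr::mutate(
        unit$truth,
        mic_contig_id = mic_id, .after = 1L
      )
      pos <- pos + unit$width + sample_range(c(300L, 800L))
    }
  }
  structure(
    list(
      records = validate_mds_records(dplyr::bind_rows(all_records)),
      truth = dplyr::bind_rows(all_truth) |>
        dplyr::arrange(.data$mac_contig_id),
      config = config
    ),
    class = "sim_architecture"
  )
}

#' @export
print.sim_architecture <- function(x, ...) {
  cat(
    "<sim_architecture>", nrow(x$records), "MDS records,",
    nrow(x$truth), "MAC contigs, seed", x$config$seed, "\n"
  )
  invisible(x)
}

#' Build the schematic three-layer nested fixture
#'
#' The canonical three-layer layout: an outer locus (default `"red"`, three
#' MDSs) whose first IES hosts a middle locus (`"blue"`, three MDSs), whose
#' first IES in turn hosts an inner nonscrambled locus (`"orange"`, three
#' MDSs). The expected metrics are IDI (red, blue, orange) = (2, 1, 0) and
#' EI = (0, 1, 2), with blue and orange embedded.
#'
#' @param mic_contig_id MIC contig id for the fixture.
#' @param ids Names of the outer, middle and inner contigs.
#' @return An MDS record tibble.
#' @export
nested_demo_records <- function(mic_contig_id = "MIC_demo",
                                ids = c("red", "blue", "orange")) {
  build <- function(mac, starts, len = 50L) {
    tibble::tibble(
      mic_contig_id = mic_contig_id, mac_contig_id = mac,
      mds_index = seq_along(starts),
      mic_start = as.integer(starts), mic_end = as.integer(starts + len - 1L),
      orientation = "forward"
    )
  }
  # red's first IES [51, 2950] hosts blue; blue's first IES [151, 2600]
  # hosts orange.
  dplyr::bind_rows(
    build(ids[1L], c(1L, 2951L, 3051L)),
    build(ids[2L], c(101L, 2601L, 2801L)),
    build(ids[3L], c(301L, 401L, 501L))
  )
}
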