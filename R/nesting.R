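#' IES intervals of one MAC contig on one MIC contig
#'
#' An internally eliminated sequence (IES) is the germline span between two
#' MDSs of the same MAC contig that are adjacent in MIC-coordinate order (not
#' MAC order — which is what makes "an IES containing another gene" well
#' defined for scrambled loci). An IES is *conventional* (nonscrambled) when
#' its flanking MDSs are consecutive in MAC order and co-oriented in reading
#' direction: `i` then `i + 1` both forward, or `i + 1` then `i` both
#' inverted. Conventional IESs correspond exactly to the adjacent identical
#' pointer pairs that [strip_trivial_pairs()] deletes.
#'
#' @param records MDS records of a single `(mic_contig_id, mac_contig_id)`
#'   pair; at least 2 records with non-overlapping MIC intervals.
#' @return A tibble with one row per adjacent pair: `mac_contig_id`,
#'   `mic_contig_id`, `start`, `end` (1-based inclusive MIC coordinates),
#'   `left_mds`, `right_mds` and `conventional`.
#' @export
ies_intervals <- function(records) {
  records <- validate_mds_records(records)
  if (length(unique(records$mic_contig_id)) != 1L ||
    length(unique(records$mac_contig_id)) != 1L) {
    stop("records must belong to a single (mic_contig_id, mac_contig_id)",
      call. = FALSE
    )
  }
  if (nrow(records) < 2L) {
    stop("need at least 2 MDS records to form an IES", call. = FALSE)
  }
  n <- nrow(records) # already sorted by (mic_start, mic_end)
  if (any(records$mic_start[-1L] <= records$mic_end[-n])) {
    stop("overlapping MDS records of the same MAC contig", call. = FALSE)
  }
  left <- records[-n, ]
  right <- records[-1L, ]
  conventional <-
    (left$orientation == "forward" & right$orientation == "forward" &
      right$mds_index == left$mds_index + 1L) |
      (left$orientation == "inverted" & right$orientation == "inverted" &
        right$mds_index == left$mds_index - 1L)
  tibble::tibble(
    mac_contig_id = records$mac_contig_id[[1]],
    mic_contig_id = records$mic_contig_id[[1]],
    start = left$mic_end + 1L,
    end = right$mic_start - 1L,
    left_mds = left$mds_index,
    right_mds = right$mds_index,
    conventional = conventional
  )
}

# All IES intervals of every MAC contig in a single-MIC-contig layout.
layout_ies <- function(layout) {
  layout |>
    dplyr::group_split(.data$mac_contig_id) |>
    purrr::keep(~ nrow(.x) >= 2L) |>
    purrr::map(ies_intervals) |>
    dplyr::bind_rows() |>
    (\(x) {
      if (nrow(x) == 0L) {
        tibble::tibble(
          mac_contig_id = character(), mic_contig_id = character(),
          start = integer(), end = integer(),
          left_mds = integer(), right_mds = integer(),
          conventional = logical()
        )
      } else {
        x
      }
    })()
}

# Proper-subset containment of [s, e] within [S, E] (1-based inclusive).
# Zero-width spans (S > E) contain nothing.
contains_strict <- function(S, E, s, e) {
  S <= E & S <= s & e <= E & (S < s | e < E)
}

check_single_mic <- function(layout) {
  layout <- validate_mds_records(layout)
  if (nrow(layout) > 0L && length(unique(layout$mic_contig_id)) != 1L) {
    stop("layout must contain MDS records of a single MIC contig",
      call. = FALSE
    )
  }
  layout
}

#' Embedding index (EI) of a MAC contig
#'
#' The EI of an MDS is the number of layers of foreign nanochromosomes
#' surrounding it: the count of distinct other MAC contigs that have an IES
#' strictly containing the MDS interval. The EI of the contig is the maximum
#' over its MDSs, so a single deeply embedded MDS sets the contig's EI.
#'
#' @param target MAC contig id.
#' @param layout All MDS records of one MIC contig (every MAC contig on it).
#' @return Integer EI (>= 0).
#' @export
ei_of_contig <- function(target, layout) {
  layout <- check_single_mic(layout)
  ies <- layout_ies(layout)
  own <- dplyr::filter(layout, .data$mac_contig_id == target)
  if (nrow(own) == 0L) {
    stop("target '", target, "' has no MDS records in the layout",
      call. = FALSE
    )
  }
  foreign <- dplyr::filter(ies, .data$mac_contig_id != target)
  if (nrow(foreign) == 0L) {
    return(0L)
  }
  per_mds <- purrr::map_int(seq_len(nrow(own)), function(r) {
    inside <- contains_strict(
      foreign$start, foreign$end, own$mic_start[r], own$mic_end[r]
    )
    length(unique(foreign$mac_contig_id[inside]))
  })
  max(per_mds)
}

#' Insertion depth index (IDI) of a MAC contig
#'
#' The IDI recursively counts nesting events on the IESs of a
#' nanochromosome: an IES containing no foreign MDS has IDI 0; otherwise its
#' IDI is 1 plus the maximum, over foreign contigs with an MDS inside it, of
#' the IDI of their IESs that lie strictly inside (0 if none descend). The
#' IDI of the contig is the maximum over its IESs. The recursion descends
#' only into strictly contained intervals, which guarantees termination even
#' when loci interleave mutually.
#'
#' @inheritParams ei_of_contig
#' @return Integer IDI (>= 0).
#' @export
idi_of_contig <- function(target, layout) {
  layout <- check_single_mic(layout)
  ies <- layout_ies(layout)
  own <- dplyr::filter(ies, .data$mac_contig_id == target)
  if (nrow(own) == 0L) {
    return(0L)
  }
  memo <- new.env(parent = emptyenv())
  max(purrr::map_int(seq_len(nrow(own)), function(r) {
    idi_of_ies(own[r, ], layout, ies, memo)
  }))
}

idi_of_ies <- function(E, layout, ies, memo) {
  key <- paste(E$mac_contig_id, E$start, E$end, sep = "|")
  if (!is.null(memo[[key]])) {
    return(memo[[key]])
  }
  foreign_mds <- dplyr::filter(
    layout,
    .data$mac_contig_id != E$mac_contig_id,
    contains_strict(E$start, E$end, .data$mic_start, .data$mic_end)
  )
  if (nrow(foreign_mds) == 0L) {
    memo[[key]] <- 0L
    return(0L)
  }
  inner <- purrr::map_int(unique(foreign_mds$mac_contig_id), function(d) {
    inner_ies <- dplyr::filter(
      ies,
      .data$mac_contig_id == d,
      contains_strict(E$start, E$end, .data$start, .data$end)
    )
    if (nrow(inner_ies) == 0L) {
      return(0L)
    }
    max(purrr::map_int(seq_len(nrow(inner_ies)), function(r) {
      idi_of_ies(inner_ies[r, ], layout, ies, memo)
    }))
  })
  res <- 1L + max(inner)
  memo[[key]] <- res
  res
}

#' Classify the nesting relationship of a pair of MAC contigs
#'
#' A contig `a` is *embedded* in `b` when all of `a`'s MDSs (on this MIC
#' contig) lie within a single IES of `b`. Two contigs are *interleaved* when
#' each has at least one MDS within an IES of the other. Exactly one category
#' is returned; embedding is mutually exclusive with interleaving because an
#' embedded contig sits wholly inside one gap of its host.
#'
#' @param a,b MAC contig ids present in the layout.
#' @inheritParams ei_of_contig
#' @return One of `"a_embedded_in_b"`, `"b_embedded_in_a"`, `"interleaved"`,
#'   `"none"`.
#' @export
classify_pair <- function(a, b, layout) {
  layout <- check_single_mic(layout)
  ies <- layout_ies(layout)
  mds_a <- dplyr::filter(layout, .data$mac_contig_id == a)
  mds_b <- dplyr::filter(layout, .data$mac_contig_id == b)
  if (nrow(mds_a) == 0L || nrow(mds_b) == 0L) {
    stop("both contigs must have MDS records in the layout", call. = FALSE)
  }
  ies_a <- dplyr::filter(ies, .data$mac_contig_id == a)
  ies_b <- dplyr::filter(ies, .data$mac_contig_id == b)
  if (embedded_in(mds_a, ies_b)) {
    return("a_embedded_in_b")
  }
  if (embedded_in(mds_b, ies_a)) {
    return("b_embedded_in_a")
  }
  if (any_mds_in_ies(mds_a, ies_b) && any_mds_in_ies(mds_b, ies_a)) {
    return("interleaved")
  }
  "none"
}

# All MDSs within one single IES of the partner?
embedded_in <- function(mds, partner_ies) {
  if (nrow(partner_ies) == 0L) {
    return(FALSE)
  }
  any(purrr::map_lgl(seq_len(nrow(partner_ies)), function(r) {
    all(contains_strict(
      partner_ies$start[r], partner_ies$end[r],
      mds$mic_start, mds$mic_end
    ))
  }))
}

any_mds_in_ies <- function(mds, partner_ies) {
  if (nrow(partner_ies) == 0L) {
    return(FALSE)
  }
  any(purrr::map_lgl(seq_len(nrow(mds)), function(r) {
    any(contains_strict(
      partner_ies$start, partner_ies$end,
      mds$mic_start[r], mds$mic_end[r]
    ))
  }))
}

#' Aggregate pairwise relationships for one contig
#'
#' Aggregates [classify_pair()] over all partner contigs on the MIC contig:
#' the target is *embedded* when it is embedded in at least one partner and
#' *interleaved* when it interleaves with at least one partner.
#'
#' @inheritParams ei_of_contig
#' @return One of `"none"`, `"embedded_only"`, `"interleaved_only"`,
#'   `"both"`.
#' @export
relationship_class <- function(target, layout) {
  layout <- check_single_mic(layout)
  partners <- setdiff(unique(layout$mac_contig_id), target)
  if (length(partners) == 0L) {
    return("none")
  }
  cls <- purrr::map_chr(partners, function(b) classify_pair(target, b, layout))
  combine_relationship(
    any(cls == "a_embedded_in_b"),
    any(cls == "interleaved")
  )
}

combine_relationship <- function(embedded, interleaved) {
  if (embedded && interleaved) {
    "both"
  } else if (embedded) {
    "embedded_only"
  } else if (interleaved) {
    "interleaved_only"
  } else {
    "none"
  }
}

#' MAC contigs excluded by the terminal-overlap filter
#'
#' MDSs mapping to distinct MAC contigs whose sequences overlap on the MIC
#' (alternatively fragmented / terminally overlapping products) are excluded
#' from the nesting analysis. Any pair of contigs with MDS intervals
#' overlapping by more than `overlap_bp` bases is dropped; short pointer-
#' scale overlaps up to the threshold are tolerated.
#'
#' @inheritParams ei_of_contig
#' @param overlap_bp Overlap tolerance in bases (default 20, pointer scale).
#' @return Character vector of excluded MAC contig ids.
#' @export
terminal_overlap_filter <- function(layout, overlap_bp = 20L) {
  layout <- check_single_mic(layout)
  n <- nrow(layout)
  if (n < 2L) {
    return(character(0))
  }
  ov <- outer(layout$mic_end, layout$mic_end, pmin) -
    outer(layout$mic_start, layout$mic_start, pmax) + 1L
  different_mac <- outer(
    layout$mac_contig_id, layout$mac_contig_id, `!=`
  )
  hit <- which(ov > overlap_bp & different_mac, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(character(0))
  }
  sort(unique(layout$mac_contig_id[c(hit[, 1L], hit[, 2L])]))
}

# Scrambledness of a possibly partial MIC-order arrangement portion:
# nonscrambled iff indices strictly increase all forward, or strictly
# decrease all inverted.
portion_scrambled <- function(mds_index, orientation) {
  if (length(mds_index) <= 1L) {
    return(FALSE)
  }
  fwd <- all(orientation == "forward") && all(diff(mds_index) > 0L)
  rev_inv <- all(orientation == "inverted") && all(diff(mds_index) < 0L)
  !(fwd || rev_inv)
}

#' Per-contig nesting report
#'
#' Runs the whole nesting analysis over a table of MDS records: applies the
#' terminal-overlap filter per MIC contig, computes IDI, EI and the
#' embedded/interleaved class on the retained layout, and flags scrambling
#' from the arrangement map. MAC contigs spread over several MIC contigs are
#' analysed per MIC-contig portion and aggregated (max IDI/EI, combined
#' relationship class, any-portion scrambled) with the map flagged
#' incomplete.
#'
#' @param records MDS records (any number of MIC/MAC contigs).
#' @param overlap_bp Passed to [terminal_overlap_filter()].
#' @return A tibble with one row per MAC contig: `mac_contig_id`, `idi`,
#'   `ei`, `relationship_class`, `scrambled`, `mds_count`, `complete`,
#'   `excluded`. Excluded contigs carry `NA` metrics.
#' @export
nesting_report <- function(records, overlap_bp = 20L) {
  records <- validate_mds_records(records)
  if (nrow(records) == 0L) {
    return(tibble::tibble(
      mac_contig_id = character(), idi = integer(), ei = integer(),
      relationship_class = character(), scrambled = logical(),
      mds_count = integer(), complete = logical(), excluded = logical()
    ))
  }
  per_portion <- records |>
    dplyr::group_split(.data$mic_contig_id) |>
    purrr::map(function(layout) {
      excluded <- terminal_overlap_filter(layout, overlap_bp = overlap_bp)
      kept <- dplyr::filter(layout, !(.data$mac_contig_id %in% excluded))
      macs <- unique(layout$mac_contig_id)
      purrr::map(macs, function(m) {
        rows <- dplyr::filter(layout, .data$mac_contig_id == m)
        if (m %in% excluded) {
          return(tibble::tibble(
            mac_contig_id = m, idi = NA_integer_, ei = NA_integer_,
            relationship_class = NA_character_,
            scrambled = portion_scrambled(rows$mds_index, rows$orientation),
            mds_count = nrow(rows), excluded = TRUE
          ))
        }
        tibble::tibble(
          mac_contig_id = m,
          idi = idi_of_contig(m, kept),
          ei = ei_of_contig(m, kept),
          relationship_class = relationship_class(m, kept),
          scrambled = portion_scrambled(rows$mds_index, rows$orientation),
          mds_count = nrow(rows),
          excluded = FALSE
        )
      }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()

  completeness <- records |>
    dplyr::group_by(.data$mac_contig_id) |>
    dplyr::summarise(
      complete = setequal(.data$mds_index, seq_len(max(.data$mds_index))) &&
        length(unique(.data$mic_contig_id)) == 1L,
      .groups = "drop"
    )
  if (any(!completeness$complete)) {
    warning(
      "incomplete arrangement map(s): ",
      paste(completeness$mac_contig_id[!completeness$complete],
        collapse = ", "
      ),
      "; scrambled status inherited from the observed portion(s)"
    )
  }

  per_portion |>
    dplyr::group_by(.data$mac_contig_id) |>
    dplyr::summarise(
      idi = if (all(is.na(.data$idi))) NA_integer_ else {
        max(.data$idi, na.rm = TRUE)
      },
      ei = if (all(is.na(.data$ei))) NA_integer_ else {
        max(.data$ei, na.rm = TRUE)
      },
      relationship_class = if (all(is.na(.data$relationship_class))) {
        NA_character_
      } else {
        combine_relationship(
          any(.data$relationship_class %in% c("embedded_only", "both"),
            na.rm = TRUE
          ),
          any(.data$relationship_class %in% c("interleaved_only", "both"),
            na.rm = TRUE
          )
        )
      },
      scrambled = any(.data$scrambled),
      mds_count = sum(.data$mds_count),
      excluded = any(.data$excluded),
      .groups = "drop"
    ) |>
    dplyr::left_join(completeness, by = "mac_contig_id") |>
    dplyr::select(
      "mac_contig_id", "idi", "ei", "relationship_class", "scrambled",
      "mds_count", "complete", "excluded"
    ) |>
    dplyr::arrange(.data$mac_contig_id)
}

#' Spearman correlation of IDI class vs scrambled proportion
#'
#' Rank correlation of the IDI class values against each class's proportion
#' of scrambled contigs, computed over class aggregates (few points; the
#' small-n caveat applies). Identical proportions across classes make the
#' rank correlation undefined; that case is flagged, not silently zeroed.
#'
#' @param idi Numeric vector of IDI class values.
#' @param proportion Scrambled proportion (any consistent scale) per class.
#' @return One-row tibble: `rho`, `p_value`, `n_classes`, `degenerate`.
#' @export
idi_scrambled_correlation <- function(idi, proportion) {
  stopifnot(length(idi) == length(proportion))
  if (length(idi) < 2L || length(unique(proportion)) < 2L ||
    length(unique(idi)) < 2L) {
    return(tibble::tibble(
      rho = NA_real_, p_value = NA_real_,
      n_classes = length(idi), degenerate = TRUE
    ))
  }
  ct <- suppressWarnings(
    stats::cor.test(idi, proportion, method = "spearman", exact = TRUE)
  )
  tibble::tibble(
    rho = unname(ct$estimate), p_value = ct$p.value,
    n_classes = length(idi), degenerate = FALSE
  )
}

#' Enrichment statistics for nesting vs scrambling
#'
#' Tests whether scrambling is enriched among nested loci: a 2x2 chi-square
#' (1 df, no continuity correction — cohort sizes are in the thousands) of
#' scrambled status against IDI >= 1, and the Spearman rank correlation of
#' IDI class against the class's scrambled proportion
#' ([idi_scrambled_correlation()]). Excluded contigs are dropped first.
#'
#' @param reports A [nesting_report()] tibble.
#' @return One-row tibble: `chi2_stat`, `chi2_df`, `chi2_p`,
#'   `chi2_degenerate`, `spearman_rho`, `spearman_p`, `spearman_degenerate`.
#' @export
enrichment_stats <- function(reports) {
  r <- dplyr::filter(reports, !.data$excluded)
  nested <- r$idi >= 1L
  chi2_degenerate <- length(unique(r$scrambled)) < 2L ||
    length(unique(nested)) < 2L
  if (chi2_degenerate) {
    chi2_stat <- NA_real_
    chi2_p <- NA_real_
  } else {
    ct <- stats::chisq.test(table(r$scrambled, nested), correct = FALSE)
    chi2_stat <- unname(ct$statistic)
    chi2_p <- ct$p.value
  }
  classes <- r |>
    dplyr::filter(.data$idi >= 1L) |>
    dplyr::group_by(.data$idi) |>
    dplyr::summarise(prop = mean(.data$scrambled), .groups = "drop")
  sp <- idi_scrambled_correlation(classes$idi, classes$prop)
  tibble::tibble(
    chi2_stat = chi2_stat, chi2_df = 1L, chi2_p = chi2_p,
    chi2_degenerate = chi2_degenerate,
    spearman_rho = sp$rho, spearman_p = sp$p_value,
    spearman_degenerate = sp$degenerate
  )
}

#' Cohort summary tables
#'
#' Tabulates a nesting report the way genome-wide cohorts are reported: per
#' IDI class and per EI class (contig count, scrambled count and percentage,
#' average MDS count), and by embedding/interleaving relationship (embedded
#' only / interleaved only / both).
#'
#' @param reports A [nesting_report()] tibble.
#' @return A list of two tibbles, `by_index` (columns `metric`, `class`,
#'   `n_contigs`, `n_scrambled`, `pct_scrambled`, `avg_mds`) and
#'   `relationships` (same counts per relationship category, all categories
#'   always present).
#' @export
summarize_nesting <- function(reports) {
  r <- dplyr::filter(reports, !.data$excluded)
  tab <- function(x, metric) {
    x |>
      dplyr::group_by(class = .data[[metric]]) |>
      dplyr::summarise(
        n_contigs = dplyr::n(),
        n_scrambled = sum(.data$scrambled),
        pct_scrambled = 100 * mean(.data$scrambled),
        avg_mds = mean(.data$mds_count),
        .groups = "drop"
      ) |>
      dplyr::mutate(metric = toupper(metric), .before = 1L)
  }
  by_index <- dplyr::bind_rows(tab(r, "idi"), tab(r, "ei"))
  categories <- c(
    "with_mds_in_other_ies", "embedded_only", "interleaved_only", "both"
  )
  rel <- r |>
    dplyr::filter(.data$relationship_class != "none") |>
    dplyr::mutate(category = .data$relationship_class)
  rel <- dplyr::bind_rows(
    dplyr::mutate(rel, category = "with_mds_in_other_ies"),
    rel
  )
  relationships <- rel |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_contigs = dplyr::n(),
      n_scrambled = sum(.data$scrambled),
      pct_scrambled = 100 * mean(.data$scrambled),
      avg_mds = mean(.data$mds_count),
      .groups = "drop"
    )
  relationships <- tibble::tibble(category = categories) |>
    dplyr::left_join(relationships, by = "category") |>
    dplyr::mutate(
      n_contigs = dplyr::coalesce(.data$n_contigs, 0L),
      n_scrambled = dplyr::coalesce(.data$n_scrambled, 0L),
      pct_scrambled = dplyr::coalesce(.data$pct_scrambled, 0),
      avg_mds = dplyr::coalesce(.data$avg_mds, 0)
    )
  list(by_index = by_index, relationships = relationships)
}
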