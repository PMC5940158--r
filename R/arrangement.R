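#' Parse signed MDS arrangement notation
#'
#' Arrangement notation writes the micronuclear (MIC) order of the
#' macronuclear-destined sequences (MDSs) of one MAC nanochromosome as
#' whitespace-separated tokens `M<i>` (forward) or `-M<i>` (inverted), e.g.
#' `"M2 M3 -M8 -M7 -M1 -M4 M5 M6"`. The index `i` is the position of the MDS
#' in the final MAC product, so the token order encodes the germline
#' scrambling of the locus.
#'
#' @param text A single string of arrangement notation.
#' @param mac_contig_id Optional MAC contig identifier attached to the map.
#' @return An `arrangement_map` object: a list with `mac_contig_id`, `k` (the
#'   largest MDS index), `entries` (a tibble with columns `mds_index` and
#'   `orientation`, in MIC order) and `complete` (`TRUE` iff the indices are
#'   exactly `1..k`). Incomplete maps are flagged, never silently accepted.
#' @examples
#' parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6")
#' @export
parse_arrangement <- function(text, mac_contig_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty arrangement notation", call. = FALSE)
  }
  bad <- !grepl("^-?M[0-9]+$", tokens)
  if (any(bad)) {
    stop(
      "malformed arrangement token(s): ",
      paste(tokens[bad], collapse = ", "),
      call. = FALSE
    )
  }
  inverted <- startsWith(tokens, "-")
  idx <- as.integer(sub("^-?M", "", tokens))
  if (any(idx < 1L)) {
    stop("MDS indices must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop(
      "duplicate MDS index in arrangement: ",
      paste(unique(idx[duplicated(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  new_arrangement_map(
    mac_contig_id = mac_contig_id,
    entries = tibble::tibble(
      mds_index = idx,
      orientation = ifelse(inverted, "inverted", "forward")
    )
  )
}

new_arrangement_map <- function(mac_contig_id, entries) {
  stopifnot(all(c("mds_index", "orientation") %in% names(entries)))
  k <- max(entries$mds_index)
  structure(
    list(
      mac_contig_id = mac_contig_id,
      k = k,
      entries = tibble::as_tibble(entries),
      complete = setequal(entries$mds_index, seq_len(k))
    ),
    class = "arrangement_map"
  )
}

#' Format an arrangement map back to notation
#'
#' Inverse of [parse_arrangement()]: `format(parse_arrangement(x))` equals the
#' whitespace-normalised form of `x`.
#'
#' @param x An `arrangement_map`.
#' @param ... Unused.
#' @return A single string in arrangement notation.
#' @export
format.arrangement_map <- function(x, ...) {
  paste0(
    ifelse(x$entries$orientation == "inverted", "-", ""),
    "M", x$entries$mds_index,
    collapse = " "
  )
}

#' @export
print.arrangement_map <- function(x, ...) {
  cat(
    "<arrangement_map",
    if (!is.na(x$mac_contig_id)) paste0("[", x$mac_contig_id, "]") else "",
    "k=", x$k,
    if (!x$complete) "(incomplete)" else "",
    ">\n ", format(x), "\n"
  )
  invisible(x)
}

#' Tidy an arrangement map into a tibble
#'
#' @param x An `arrangement_map`.
#' @param ... Unused.
#' @return A tibble with one row per MDS in MIC order: `mic_position`,
#'   `mds_index`, `orientation`, `mac_contig_id`.
#' @export
tidy.arrangement_map <- function(x, ...) {
  tibble::tibble(
    mac_contig_id = x$mac_contig_id,
    mic_position = seq_len(nrow(x$entries)),
    mds_index = x$entries$mds_index,
    orientation = x$entries$orientation
  )
}

#' Is a rearrangement map scrambled?
#'
#' A locus is nonscrambled when its MDSs keep their order and relative
#' orientation with respect to the MAC product: either `1..k` all forward, or
#' the whole-locus inversion `k..1` all inverted. Everything else is
#' scrambled (out of order and/or orientation).
#'
#' @param map A complete `arrangement_map`.
#' @return `TRUE` if scrambled, `FALSE` otherwise.
#' @examples
#' is_scrambled(parse_arrangement("M1 M2 M3"))        # FALSE
#' is_scrambled(parse_arrangement("-M3 -M2 -M1"))     # FALSE: whole-locus inversion
#' is_scrambled(parse_arrangement("M1 -M2 -M3"))      # TRUE
#' @export
is_scrambled <- function(map) {
  stopifnot(inherits(map, "arrangement_map"))
  if (!map$complete) {
    stop("is_scrambled() requires a complete arrangement map", call. = FALSE)
  }
  k <- map$k
  identity_fwd <- identical(map$entries$mds_index, seq_len(k)) &&
    all(map$entries$orientation == "forward")
  inverted_rev <- identical(map$entries$mds_index, rev(seq_len(k))) &&
    all(map$entries$orientation == "inverted")
  !(identity_fwd || inverted_rev)
}

#' Validate a tibble of MDS records
#'
#' An MDS record describes one germline occurrence of a macronuclear-destined
#' sequence: where it sits on the MIC contig, which MAC contig it belongs to,
#' its index in the final MAC order, and its orientation.
#'
#' @param records A data frame with columns `mic_contig_id`, `mac_contig_id`,
#'   `mds_index`, `mic_start`, `mic_end`, `orientation`.
#' @return The records as a tibble, sorted by
#'   `(mic_contig_id, mic_start, mic_end, mac_contig_id)` for determinism.
#' @export
validate_mds_records <- function(records) {
  required <- c(
    "mic_contig_id", "mac_contig_id", "mds_index",
    "mic_start", "mic_end", "orientation"
  )
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("missing MDS record column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  records <- tibble::as_tibble(records)
  records$mds_index <- as.integer(records$mds_index)
  records$mic_start <- as.integer(records$mic_start)
  records$mic_end <- as.integer(records$mic_end)
  if (any(records$mds_index < 1L)) {
    stop("mds_index must be >= 1", call. = FALSE)
  }
  if (any(records$mic_start > records$mic_end)) {
    stop("mic_start must be <= mic_end", call. = FALSE)
  }
  if (!all(records$orientation %in% c("forward", "inverted"))) {
    stop("orientation must be 'forward' or 'inverted'", call. = FALSE)
  }
  dup <- records |>
    dplyr::count(.data$mic_contig_id, .data$mac_contig_id, .data$mds_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate mds_index within (mic_contig_id, mac_contig_id)",
      call. = FALSE
    )
  }
  records |>
    dplyr::select(dplyr::all_of(required), dplyr::everything()) |>
    dplyr::arrange(
      .data$mic_contig_id, .data$mic_start, .data$mic_end, .data$mac_contig_id
    )
}

#' Build an arrangement map from MDS records
#'
#' Takes the MDS records of one (MIC contig, MAC contig) pair and reads off
#' the signed arrangement in MIC-coordinate order. Maps whose indices are not
#' exactly `1..k` (e.g. a MAC contig whose MDSs are spread over several MIC
#' contigs) come back flagged incomplete.
#'
#' @param records MDS records for a single `(mic_contig_id, mac_contig_id)`.
#' @return An `arrangement_map`.
#' @export
arrangement_from_records <- function(records) {
  records <- validate_mds_records(records)
  if (length(unique(records$mic_contig_id)) != 1L ||
    length(unique(records$mac_contig_id)) != 1L) {
    stop("records must belong to a single (mic_contig_id, mac_contig_id)",
      call. = FALSE
    )
  }
  new_arrangement_map(
    mac_contig_id = records$mac_contig_id[[1]],
    entries = tibble::tibble(
      mds_index = records$mds_index,
      orientation = records$orientation
    )
  )
}
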