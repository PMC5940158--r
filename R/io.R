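#' GFF dialect configuration
#'
#' MDS annotation tables come as 9-column GFF whose attribute schema varies
#' by source, so the attribute keys are configurable. The defaults match the
#' files this package writes: `mac_contig=<id>;mds_index=<i>;orientation=
#' forward|inverted`. When the orientation attribute is absent, the strand
#' column is used (`-` maps to inverted; `+` and `.` to forward).
#'
#' @param mac_attr Attribute key holding the MAC contig id.
#' @param index_attr Attribute key holding the MDS index.
#' @param orientation_attr Attribute key holding the orientation (optional in
#'   the file; see above).
#' @param feature_types GFF `type` values treated as MDS features; all other
#'   features are ignored (not counted as skipped).
#' @return A `gff_dialect` list.
#' @export
gff_dialect <- function(mac_attr = "mac_contig",
                        index_attr = "mds_index",
                        orientation_attr = "orientation",
                        feature_types = c("MDS", "mds")) {
  structure(
    list(
      mac_attr = mac_attr, index_attr = index_attr,
      orientation_attr = orientation_attr, feature_types = feature_types
    ),
    class = "gff_dialect"
  )
}

#' Read a dialect configuration from YAML
#'
#' @param path YAML file with any of the keys `mac_attr`, `index_attr`,
#'   `orientation_attr`, `feature_types`; missing keys take the
#'   [gff_dialect()] defaults.
#' @return A `gff_dialect`.
#' @export
read_dialect_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(gff_dialect, cfg[names(cfg) %in% names(formals(gff_dialect))])
}

gff_attr <- function(attributes, key) {
  m <- stringr::str_match(
    attributes,
    paste0("(?:^|;)\\s*", key, "=([^;]*)")
  )
  trimws(m[, 2L])
}

#' Read an MDS annotation table (GFF dialect)
#'
#' Parses a 9-column tab-separated GFF into MDS records. Lines that are
#' comments or non-MDS features are ignored; malformed lines (wrong field
#' count, bad coordinates, missing mandatory attributes) are skipped and
#' reported, never silently dropped.
#'
#' @param path Path to the GFF file.
#' @param dialect A [gff_dialect()].
#' @return An `mds_annotation` object: list with `records` (validated MDS
#'   record tibble), `skipped` (tibble `line`, `reason`) and `dialect`.
#' @export
read_mds_gff <- function(path, dialect = gff_dialect()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  skipped <- list()
  rows <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      skipped[[length(skipped) + 1L]] <-
        list(line = line_no[i], reason = "field_count")
      next
    }
    if (!(fields[3L] %in% dialect$feature_types)) {
      next
    }
    start <- suppressWarnings(as.integer(fields[4L]))
    end <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start) || is.na(end) || start < 1L || start > end) {
      skipped[[length(skipped) + 1L]] <-
        list(line = line_no[i], reason = "malformed_coordinates")
      next
    }
    mac <- gff_attr(fields[9L], dialect$mac_attr)
    idx <- suppressWarnings(as.integer(gff_attr(fields[9L], dialect$index_attr)))
    if (is.na(mac) || !nzchar(mac) || is.na(idx)) {
      skipped[[length(skipped) + 1L]] <-
        list(line = line_no[i], reason = "missing_attribute")
      next
    }
    ori <- gff_attr(fields[9L], dialect$orientation_attr)
    if (is.na(ori) || !nzchar(ori)) {
      ori <- if (identical(fields[7L], "-")) "inverted" else "forward"
    }
    if (!ori %in% c("forward", "inverted")) {
      skipped[[length(skipped) + 1L]] <-
        list(line = line_no[i], reason = "bad_orientation")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mic_contig_id = fields[1L], mac_contig_id = mac, mds_index = idx,
      mic_start = start, mic_end = end, orientation = ori
    )
  }
  records <- if (length(rows)) {
    validate_mds_records(dplyr::bind_rows(rows))
  } else {
    tibble::tibble(
      mic_contig_id = character(), mac_contig_id = character(),
      mds_index = integer(), mic_start = integer(), mic_end = integer(),
      orientation = character()
    )
  }
  skipped_tbl <- if (length(skipped)) {
    dplyr::bind_rows(lapply(skipped, tibble::as_tibble))
  } else {
    tibble::tibble(line = integer(), reason = character())
  }
  if (nrow(skipped_tbl) > 0L) {
    message(
      "read_mds_gff: skipped ", nrow(skipped_tbl), " line(s): ",
      paste(
        sprintf("%d (%s)", skipped_tbl$line, skipped_tbl$reason),
        collapse = ", "
      )
    )
  }
  structure(
    list(records = records, skipped = skipped_tbl, dialect = dialect),
    class = "mds_annotation"
  )
}

#' @export
print.mds_annotation <- function(x, ...) {
  cat(
    "<mds_annotation>", nrow(x$records), "MDS records,",
    nrow(x$skipped), "skipped line(s)\n"
  )
  print(x$records)
  invisible(x)
}

#' Tidy an annotation into its record tibble
#'
#' @param x An `mds_annotation`.
#' @param ... Unused.
#' @export
tidy.mds_annotation <- function(x, ...) x$records

#' Write MDS records as a GFF dialect file
#'
#' Deterministic 9-column output (stable record order from
#' [validate_mds_records()]); round-trips through [read_mds_gff()].
#'
#' @param records MDS record tibble.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_mds_gff <- function(records, path, source = "scramblekit") {
  records <- validate_mds_records(records)
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\t%s\tMDS\t%d\t%d\t.\t%s\t.\tID=%s.MDS%d;mac_contig=%s;mds_index=%d;orientation=%s",
      records$mic_contig_id, source, records$mic_start, records$mic_end,
      ifelse(records$orientation == "inverted", "-", "+"),
      records$mac_contig_id, records$mds_index,
      records$mac_contig_id, records$mds_index, records$orientation
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read arrangement-notation files
#'
#' One map per line, `<mac_id>TAB<notation>`; blank lines and `#` comments
#' ignored.
#'
#' @param path Input path.
#' @return A tibble with `mac_contig_id`, `notation` and a list-column `map`
#'   of `arrangement_map` objects.
#' @export
read_arrangements <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed arrangement line(s): expected '<mac_id>\\t<notation>'",
      call. = FALSE
    )
  }
  tibble::tibble(
    mac_contig_id = purrr::map_chr(parts, 1L),
    notation = purrr::map_chr(parts, 2L),
    map = purrr::map2(
      purrr::map_chr(parts, 2L), purrr::map_chr(parts, 1L),
      parse_arrangement
    )
  )
}

#' Write analysis reports as TSV
#'
#' Writes the per-contig nesting report (sorted by `mac_contig_id`, fixed
#' column order, header) and optionally reduction traces, under a common
#' path prefix.
#'
#' @param reports A [nesting_report()] tibble.
#' @param traces Optional named list of `reduction_trace` objects (names =
#'   MAC contig ids).
#' @param path_prefix Output prefix; files written are
#'   `<prefix>_nesting.tsv` and `<prefix>_traces.tsv`.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(reports, traces = NULL, path_prefix) {
  out <- character(0)
  nesting_path <- paste0(path_prefix, "_nesting.tsv")
  reports |>
    dplyr::arrange(.data$mac_contig_id) |>
    readr::write_tsv(nesting_path)
  out <- c(out, nesting_path)
  if (!is.null(traces)) {
    trace_path <- paste0(path_prefix, "_traces.tsv")
    purrr::imap(traces, function(tr, id) {
      dplyr::mutate(tidy(tr), mac_contig_id = id, .before = 1L)
    }) |>
      dplyr::bind_rows() |>
      readr::write_tsv(trace_path)
    out <- c(out, trace_path)
  }
  invisible(out)
}
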