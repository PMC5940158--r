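#' Double occurrence words
#'
#' A double occurrence word (DOW) is a sequence of pointer labels (positive
#' integers) in which every label present occurs exactly twice. The empty
#' word is a valid DOW. Pointers are the short repeats (microhomologies)
#' flanking recombination junctions in ciliate germline loci; the DOW records
#' their order of appearance along the MIC contig.
#'
#' @param symbols Integer vector of pointer labels (possibly empty).
#' @return A `dow` object (an integer vector with class `dow`).
#' @examples
#' dow(c(1, 2, 1, 2))
#' parse_dow("12341243")
#' @export
dow <- function(symbols = integer()) {
  symbols <- as.integer(symbols)
  if (anyNA(symbols) || any(symbols < 1L)) {
    stop("DOW labels must be positive integers", call. = FALSE)
  }
  counts <- table(symbols)
  if (length(counts) && any(counts != 2L)) {
    bad <- names(counts)[counts != 2L]
    stop(
      "not a double occurrence word; label(s) not occurring exactly twice: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(symbols, class = "dow")
}

#' @rdname dow
#' @param text Serialized word: concatenated digits when all labels are <= 9
#'   (e.g. `"12341243"`), comma-separated otherwise (e.g.
#'   `"4,10,11,8,12,11,9,8,4,9,10,12"`). The empty string is the empty word.
#' @export
parse_dow <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) {
    return(dow())
  }
  if (grepl(",", text, fixed = TRUE)) {
    parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
    if (any(!grepl("^[0-9]+$", parts))) {
      stop("malformed comma-separated word: ", text, call. = FALSE)
    }
    return(dow(as.integer(parts)))
  }
  if (!grepl("^[0-9]+$", text)) {
    stop("malformed word: ", text, call. = FALSE)
  }
  digits <- as.integer(strsplit(text, "", fixed = TRUE)[[1]])
  if (any(digits == 0L)) {
    stop(
      "digit-string words cannot contain '0'; ",
      "use comma separators for labels >= 10",
      call. = FALSE
    )
  }
  dow(digits)
}

#' Serialize a DOW
#'
#' Digit string when every label is a single digit, comma-separated
#' otherwise; the empty word serializes to `""`.
#'
#' @param x A `dow`.
#' @param ... Unused.
#' @export
format.dow <- function(x, ...) {
  if (length(x) == 0L) {
    return("")
  }
  if (max(x) > 9L) {
    paste(unclass(x), collapse = ",")
  } else {
    paste(unclass(x), collapse = "")
  }
}

#' @export
print.dow <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<dow> ε (empty word)\n")
  } else {
    cat("<dow>", format(x), "\n")
  }
  invisible(x)
}

#' @export
as.character.dow <- function(x, ...) format(x)

dow_labels <- function(w) unique(as.integer(w))

#' Pointer double occurrence word of an arrangement
#'
#' Scanning the MDSs of a complete rearrangement map in MIC order, a forward
#' MDS with index `i` emits the pointer pair `(i - 1, i)` and an inverted MDS
#' emits `(i, i - 1)`; the terminal MDSs emit a single pointer (index 1 emits
#' only pointer 1, index `k` only pointer `k - 1`). The concatenation of all
#' emissions is the pointer word of the locus, a DOW over labels
#' `1..(k - 1)`. A nonscrambled map yields adjacent identical pairs only,
#' e.g. `M1 M2 M3` gives `1122`.
#'
#' @param map A complete `arrangement_map` with `k >= 2`.
#' @return A `dow`.
#' @examples
#' format(pointer_word(parse_arrangement("M1 M3 M5 M7 -M6 -M4 -M2")))
#' @export
pointer_word <- function(map) {
  stopifnot(inherits(map, "arrangement_map"))
  if (!map$complete) {
    stop("pointer_word() requires a complete arrangement map", call. = FALSE)
  }
  k <- map$k
  if (k < 2L) {
    warning("arrangement has a single MDS; pointer word is empty")
    return(dow())
  }
  emissions <- purrr::map2(
    map$entries$mds_index, map$entries$orientation,
    function(i, ori) {
      p <- if (ori == "forward") c(i - 1L, i) else c(i, i - 1L)
      p[p >= 1L & p <= k - 1L]
    }
  )
  dow(unlist(emissions, use.names = FALSE))
}

#' Remove adjacent identical pointer pairs
#'
#' Adjacent identical pointers flank conventional (nonscrambled) IESs and
#' carry no scrambling information, so they are stripped before pattern
#' analysis. Deletion cascades: removing one pair may bring two equal
#' symbols together, and those are deleted too, until none remain.
#'
#' @param w A `dow`.
#' @return A list with `word` (the stripped `dow`) and `removed` (number of
#'   pairs deleted, i.e. the number of conventional IESs).
#' @examples
#' strip_trivial_pairs(parse_dow("1122"))
#' @export
strip_trivial_pairs <- function(w) {
  stopifnot(inherits(w, "dow"))
  stack <- integer(0)
  removed <- 0L
  for (s in as.integer(w)) {
    if (length(stack) > 0L && stack[length(stack)] == s) {
      stack <- stack[-length(stack)]
      removed <- removed + 1L
    } else {
      stack <- c(stack, s)
    }
  }
  list(word = dow(stack), removed = removed)
}

#' Renumber a word's labels by rank
#'
#' Replaces the labels of a word by `1..n`, preserving the numeric order of
#' the surviving labels (the smallest label becomes 1, and so on). Used after
#' trivial-pair stripping to present the scrambled pointer word the way
#' merged-and-renumbered rearrangement maps are written.
#'
#' @param w A `dow`.
#' @return A `dow` over labels `1..n`.
#' @examples
#' format(renumber_by_rank(parse_dow("1,3,6,1,4,3,4,6")))  # "12413234"
#' @export
renumber_by_rank <- function(w) {
  stopifnot(inherits(w, "dow"))
  if (length(w) == 0L) {
    return(w)
  }
  dow(match(as.integer(w), sort(dow_labels(w))))
}

#' Number of distinct (scrambled) pointers in a word
#'
#' After trivial-pair stripping, every surviving label is a scrambled pointer
#' junction, so the distinct-label count of a residual word is its scrambled
#' pointer count.
#'
#' @param w A `dow`.
#' @return Integer count of distinct labels.
#' @export
scrambled_pointer_count <- function(w) {
  stopifnot(inherits(w, "dow"))
  length(dow_labels(w))
}

canonical_dow <- function(w) {
  x <- as.integer(w)
  if (length(x) == 0L) {
    return(integer(0))
  }
  match(x, unique(x))
}

#' Are two words isomorphic as DOWs?
#'
#' Two DOWs are isomorphic when relabeling each word's symbols in order of
#' first occurrence yields the same canonical word; i.e. they have the same
#' interleaving pattern regardless of the label values.
#'
#' @param w1,w2 `dow` objects.
#' @return `TRUE` or `FALSE`.
#' @examples
#' dow_isomorphic(parse_dow("1313"), parse_dow("1212"))  # TRUE
#' dow_isomorphic(parse_dow("1212"), parse_dow("1122"))  # FALSE
#' @export
dow_isomorphic <- function(w1, w2) {
  stopifnot(inherits(w1, "dow"), inherits(w2, "dow"))
  identical(canonical_dow(w1), canonical_dow(w2))
}
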