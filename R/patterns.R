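#' Find repeat and return patterns in a DOW
#'
#' A *repeat word* is a pair of disjoint, contiguous factor occurrences of
#' the same word `u` (e.g. `12...12`); a *return word* pairs `u` with its
#' reversal (e.g. `1234...4321`). Both require `|u| >= 2`. A hit is *maximal*
#' when `u` can be extended in neither direction while keeping both
#' occurrences factors and disjoint. Adjacent identical single symbols
#' (trivial pairs, the conventional-IES channel) are reported separately with
#' kind `"trivial_pair"`.
#'
#' Because each label occurs exactly twice in a DOW, the factor `u` of any
#' repeat/return hit has distinct labels, and removing both occurrence spans
#' deletes complete label pairs, so every removal leaves a valid DOW.
#'
#' @param w A `dow`.
#' @return A tibble with one row per hit: `kind` (`"repeat"`, `"return"` or
#'   `"trivial_pair"`), `u` (serialized factor), `length` (`|u|`), `start_a`,
#'   `start_b` (1-based start offsets of the two occurrences) and `maximal`.
#'   Zero rows when the word admits no hit (an irreducible word).
#' @examples
#' find_patterns(parse_dow("12341243"))
#' nrow(find_patterns(parse_dow("4,10,11,8,12,11,9,8,4,9,10,12")))  # 0
#' @export
find_patterns <- function(w) {
  stopifnot(inherits(w, "dow"))
  x <- as.integer(w)
  n <- length(x)
  rows <- list()
  if (n >= 4L) {
    for (L in 2:(n %/% 2L)) {
      for (i in seq_len(n - 2L * L + 1L)) {
        a <- x[i:(i + L - 1L)]
        for (j in seq.int(i + L, n - L + 1L)) {
          b <- x[j:(j + L - 1L)]
          if (identical(a, b)) {
            rows[[length(rows) + 1L]] <- list(
              kind = "repeat", i = i, j = j, L = L,
              maximal = is_maximal_hit(x, "repeat", i, j, L)
            )
          }
          if (identical(a, rev(b))) {
            rows[[length(rows) + 1L]] <- list(
              kind = "return", i = i, j = j, L = L,
              maximal = is_maximal_hit(x, "return", i, j, L)
            )
          }
        }
      }
    }
  }
  if (n >= 2L) {
    for (p in seq_len(n - 1L)) {
      if (x[p] == x[p + 1L]) {
        rows[[length(rows) + 1L]] <- list(
          kind = "trivial_pair", i = p, j = p + 1L, L = 1L, maximal = TRUE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      kind = character(), u = character(), length = integer(),
      start_a = integer(), start_b = integer(), maximal = logical()
    ))
  }
  tibble::tibble(
    kind = purrr::map_chr(rows, "kind"),
    u = purrr::map_chr(rows, function(r) {
      format(structure(x[r$i:(r$i + r$L - 1L)], class = "dow"))
    }),
    length = purrr::map_int(rows, "L"),
    start_a = purrr::map_int(rows, "i"),
    start_b = purrr::map_int(rows, "j"),
    maximal = purrr::map_lgl(rows, "maximal")
  ) |>
    dplyr::arrange(
      dplyr::desc(.data$length), .data$start_a, .data$start_b, .data$kind
    )
}

# Can the hit (i, j, L) of the given kind be extended by one symbol in either
# direction, keeping both occurrences factors of x and the spans disjoint?
is_maximal_hit <- function(x, kind, i, j, L) {
  n <- length(x)
  if (kind == "repeat") {
    # extend left: occurrences (i-1, j-1, L+1)
    left_ok <- i > 1L && (j - 1L) >= (i - 1L) + (L + 1L) &&
      x[i - 1L] == x[j - 1L]
    # extend right: occurrences (i, j, L+1)
    right_ok <- (j + L) <= n && j >= i + L + 1L && x[i + L] == x[j + L]
  } else {
    # return: u at i, rev(u) at j
    # extend u left => second occurrence gains a symbol at its end
    left_ok <- i > 1L && (j + L) <= n && x[i - 1L] == x[j + L]
    # extend u right => second occurrence gains a symbol at its front
    right_ok <- (i + L) < (j - 1L) && x[i + L] == x[j - 1L]
  }
  !(left_ok || right_ok)
}

remove_spans <- function(x, i, j, L) {
  x[-c(i:(i + L - 1L), j:(j + L - 1L))]
}

serialize_raw <- function(x) format(structure(as.integer(x), class = "dow"))

empty_steps <- function() {
  tibble::tibble(
    step = integer(), kind = character(), u = character(),
    start_a = integer(), start_b = integer(),
    word_before = character(), word_after = character()
  )
}

new_reduction_trace <- function(input, steps, residual, strategy) {
  structure(
    list(
      input = input,
      steps = steps,
      residual = residual,
      fully_reduced = length(residual) == 0L,
      strategy = strategy
    ),
    class = "reduction_trace"
  )
}

#' Reduce a DOW by iterated repeat/return removal
#'
#' Characterises the topological complexity of a scrambled locus by
#' recursively deleting repeat and return words (both occurrence spans
#' removed together) and trivial pairs. A word is *fully reduced* when some
#' removal sequence reaches the empty word; words on which no removal applies
#' are *irreducible*.
#'
#' Removal order can matter, so two strategies are exposed:
#' \describe{
#'   \item{`greedy`}{deterministic one-pass heuristic: trivial pairs not
#'     covered by a maximal pattern hit are stripped first (stripping an
#'     adjacent pair never destroys reducibility, while removing a pattern
#'     hit across it can); then the longest maximal hit, breaking ties by
#'     the innermost hit (smallest total extent — a pattern nested between
#'     the occurrences of another is removed first), then leftmost. This is
#'     the strategy behind all reported residuals.}
#'   \item{`exhaustive`}{backtracking over every hit (repeat/return of any
#'     maximality, and trivial pairs) with memoization on canonicalized
#'     words; returns a trace reaching the empty word if any removal order
#'     does, otherwise a trace to a minimal-length residual. This is the
#'     strategy that decides reducibility.}
#' }
#'
#' The reduction need not mirror the biological descrambling pathway; it is a
#' complexity measure only.
#'
#' @param w A `dow`.
#' @param strategy `"greedy"` or `"exhaustive"`.
#' @param max_labels_exhaustive Symbol budget for the exhaustive search;
#'   words with more distinct labels fall back to greedy with a warning.
#' @return A `reduction_trace`: list with `input`, `steps` (tibble: `step`,
#'   `kind`, `u`, `start_a`, `start_b`, `word_before`, `word_after`),
#'   `residual` (a `dow`), `fully_reduced` and `strategy`.
#' @examples
#' reduce_dow(parse_dow("12341243"))            # 2 steps to the empty word
#' reduce_dow(parse_dow("121342566534"))        # 5665 + 3434 then 1212
#' @export
reduce_dow <- function(w, strategy = c("greedy", "exhaustive"),
                       max_labels_exhaustive = 40L) {
  stopifnot(inherits(w, "dow"))
  strategy <- match.arg(strategy)
  if (strategy == "exhaustive" &&
    scrambled_pointer_count(w) > max_labels_exhaustive) {
    warning(
      "word exceeds the exhaustive symbol budget (",
      max_labels_exhaustive, " labels); falling back to greedy"
    )
    strategy <- "greedy"
  }
  if (strategy == "greedy") {
    reduce_greedy(w)
  } else {
    reduce_exhaustive(w)
  }
}

# Maximal repeat/return hits sorted for the greedy order: longest u first,
# then innermost (smallest total extent, so a pattern nested between the
# occurrences of another is removed first), then leftmost.
pattern_moves <- function(hits) {
  dplyr::filter(hits, .data$kind != "trivial_pair", .data$maximal) |>
    dplyr::mutate(extent = .data$start_b + .data$length - .data$start_a) |>
    dplyr::arrange(
      dplyr::desc(.data$length), .data$extent, .data$start_a, .data$start_b
    ) |>
    dplyr::select(-"extent")
}

# Trivial pairs not covered by a maximal pattern hit. A trivial pair ii can
# intersect a pattern hit only as the centre of an adjacent return word
# (v i | i rev(v)): both copies of i must lie in different occurrence spans,
# which forces the spans to abut there. Removing that hit deletes the pair
# anyway, so covered pairs are left to the pattern removal (this keeps the
# published traces, e.g. 3443 removed as one return word). Every other
# adjacent pair is deleted first: stripping it never destroys reducibility,
# while removing a pattern hit across it can (in 561143564232, the pair 11
# must go before the repeat 56.56 to expose the longer repeat 564.564).
free_trivial_moves <- function(hits) {
  tp <- dplyr::filter(hits, .data$kind == "trivial_pair")
  if (nrow(tp) == 0L) {
    return(tp)
  }
  ph <- dplyr::filter(hits, .data$kind != "trivial_pair", .data$maximal)
  covered <- vapply(seq_len(nrow(tp)), function(r) {
    p <- tp$start_a[r]
    any(vapply(seq_len(nrow(ph)), function(h) {
      span <- c(
        seq.int(ph$start_a[h], ph$start_a[h] + ph$length[h] - 1L),
        seq.int(ph$start_b[h], ph$start_b[h] + ph$length[h] - 1L)
      )
      all(c(p, p + 1L) %in% span)
    }, logical(1)))
  }, logical(1))
  tp[!covered, ]
}

# The deterministic greedy move: first free trivial pair if any, else the
# top-ranked maximal pattern hit. Zero rows when the word is irreducible.
greedy_move <- function(x) {
  hits <- find_patterns(structure(x, class = "dow"))
  tp <- free_trivial_moves(hits)
  if (nrow(tp) > 0L) {
    return(tp[1L, ])
  }
  pattern_moves(hits) |> dplyr::slice_head(n = 1L)
}

apply_move <- function(x, move) {
  remove_spans(x, move$start_a, move$start_b, move$length)
}

reduce_greedy <- function(w) {
  x <- as.integer(w)
  steps <- list()
  repeat {
    moves <- greedy_move(x)
    if (nrow(moves) == 0L) break
    m <- moves[1L, ]
    after <- apply_move(x, m)
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, kind = m$kind, u = m$u,
      start_a = m$start_a, start_b = m$start_b,
      word_before = serialize_raw(x), word_after = serialize_raw(after)
    )
    x <- after
  }
  new_reduction_trace(
    input = w,
    steps = if (length(steps)) dplyr::bind_rows(steps) else empty_steps(),
    residual = dow(x),
    strategy = "greedy"
  )
}

# Exhaustive moves: every repeat/return hit (maximal or not) and every
# trivial pair. Restricting to maximal hits would be incomplete: removal
# order can matter, and the search must decide reducibility over ALL orders.
# Maximal hits are tried first so the trace reconstruction prefers them.
exhaustive_moves <- function(x) {
  find_patterns(structure(x, class = "dow")) |>
    dplyr::arrange(
      dplyr::desc(.data$maximal), dplyr::desc(.data$length),
      .data$start_a, .data$start_b
    )
}

reduce_exhaustive <- function(w) {
  memo <- new.env(parent = emptyenv())

  best_residual_len <- function(x) {
    key <- paste0("w:", paste(match(x, unique(x)), collapse = ","))
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    memo[[key]] <- length(x) # provisional (removals strictly shrink: a DAG)
    moves <- exhaustive_moves(x)
    best <- length(x)
    if (nrow(moves) > 0L) {
      for (r in seq_len(nrow(moves))) {
        cand <- best_residual_len(apply_move(x, moves[r, ]))
        if (cand < best) best <- cand
        if (best == 0L) break
      }
    }
    memo[[key]] <- best
    best
  }

  x <- as.integer(w)
  target <- best_residual_len(x)
  steps <- list()
  while (length(x) > target) {
    moves <- exhaustive_moves(x)
    chosen <- NULL
    for (r in seq_len(nrow(moves))) {
      if (best_residual_len(apply_move(x, moves[r, ])) == target) {
        chosen <- moves[r, ]
        break
      }
    }
    stopifnot(!is.null(chosen)) # an optimal move always exists above target
    after <- apply_move(x, chosen)
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L, kind = chosen$kind, u = chosen$u,
      start_a = chosen$start_a, start_b = chosen$start_b,
      word_before = serialize_raw(x), word_after = serialize_raw(after)
    )
    x <- after
  }
  new_reduction_trace(
    input = w,
    steps = if (length(steps)) dplyr::bind_rows(steps) else empty_steps(),
    residual = dow(x),
    strategy = "exhaustive"
  )
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(
    "<reduction_trace>", format(x$input), "->",
    if (x$fully_reduced) "ε" else format(x$residual),
    sprintf("(%d step%s, %s)\n", nrow(x$steps),
      if (nrow(x$steps) == 1L) "" else "s", x$strategy
    )
  )
  if (nrow(x$steps) > 0L) print(x$steps)
  invisible(x)
}

#' Tidy a reduction trace
#'
#' @param x A `reduction_trace`.
#' @param ... Unused.
#' @return The step tibble, one row per removal.
#' @export
tidy.reduction_trace <- function(x, ...) x$steps

#' One-row summary of a reduction trace
#'
#' @param x A `reduction_trace`.
#' @param ... Unused.
#' @return A one-row tibble with the input and residual words, step count,
#'   scrambled pointer count of the residual and the `fully_reduced` flag.
#' @export
glance.reduction_trace <- function(x, ...) {
  tibble::tibble(
    input = format(x$input),
    residual = format(x$residual),
    n_steps = nrow(x$steps),
    residual_pointers = scrambled_pointer_count(x$residual),
    fully_reduced = x$fully_reduced,
    strategy = x$strategy
  )
}

#' Tangled cord words
#'
#' The tangled cord family is defined recursively on DOWs: `TC(1) = 1212`,
#' and `TC(n)` is obtained from `TC(n - 1)` by inserting the new label
#' `n + 1` immediately after the penultimate symbol and again after the last
#' symbol. `TC(n)` has `n + 1` labels and length `2n + 2`; its chord diagram
#' is a chain of slinky-like coiled circles. `TC(n)` is irreducible under
#' repeat/return removal for `n >= 2`, which makes these the archetypal
#' atypically scrambled patterns; `TC(1)` is itself a repeat word.
#'
#' @param n Cord size, `n >= 1`.
#' @return The `dow` `TC(n)`.
#' @examples
#' format(tangled_cord(1))  # "1212"
#' format(tangled_cord(2))  # "121323"
#' format(tangled_cord(3))  # "12132434"
#' @export
tangled_cord <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  x <- c(1L, 2L, 1L, 2L)
  if (n > 1L) {
    for (m in 2:n) {
      len <- length(x)
      lab <- m + 1L
      x <- c(x[seq_len(len - 1L)], lab, x[len], lab)
    }
  }
  dow(x)
}

#' Detect an embedded tangled cord
#'
#' Searches for the largest `n >= min_n` such that restricting `w` to some
#' subset of its labels (keeping symbol order) yields a word order-isomorphic
#' to `TC(n)` — i.e. the tangled cord survives after the other pointers are
#' recombined or removed. By default matching is on the linear word; cyclic
#' rotations and reversal of the restriction can be enabled.
#'
#' The default `min_n = 2` excludes `TC(1) = 1212`, which is an ordinary
#' repeat word (it equally describes an odd-even map) and would fire on any
#' repeat pattern.
#'
#' @param w A `dow`.
#' @param min_n Smallest cord size to report (default 2).
#' @param cyclic Also match cyclic rotations of the restricted word.
#' @param reversal Also match the reversed restricted word.
#' @return The largest matching `n`, or `0` if none.
#' @examples
#' contains_tangled_cord(parse_dow("12413234"))  # 2 (delete label 4)
#' contains_tangled_cord(parse_dow("1122"))      # 0
#' @export
contains_tangled_cord <- function(w, min_n = 2L, cyclic = FALSE,
                                  reversal = FALSE) {
  stopifnot(inherits(w, "dow"), min_n >= 1L)
  labels <- sort(dow_labels(w))
  m <- length(labels)
  if (m > 20L) {
    stop(
      "tangled-cord search enumerates label subsets and is limited to 20 ",
      "labels; reduce the word first",
      call. = FALSE
    )
  }
  x <- as.integer(w)
  min_size <- as.integer(min_n) + 1L
  if (m < min_size) {
    return(0L)
  }
  for (size in seq.int(m, min_size)) {
    target <- canonical_dow(tangled_cord(size - 1L))
    subsets <- utils::combn(labels, size, simplify = FALSE)
    for (S in subsets) {
      sub <- x[x %in% S]
      if (matches_pattern(sub, target, cyclic = cyclic, reversal = reversal)) {
        return(size - 1L)
      }
    }
  }
  0L
}

matches_pattern <- function(sub, target_canonical, cyclic, reversal) {
  variants <- list(sub)
  if (reversal) variants <- c(variants, list(rev(sub)))
  if (cyclic) {
    n <- length(sub)
    rots <- lapply(seq_len(n - 1L), function(r) c(sub[-seq_len(r)], sub[seq_len(r)]))
    variants <- c(variants, rots)
    if (reversal) variants <- c(variants, lapply(rots, rev))
  }
  for (v in variants) {
    if (identical(match(v, unique(v)), target_canonical)) {
      return(TRUE)
    }
  }
  FALSE
}
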