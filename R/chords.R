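#' Chord diagram layout of a DOW
#'
#' The symbols of the word are placed clockwise on a circle starting at a
#' reference mark (position 0); each label's two occurrences are joined by a
#' chord. Chords are categorised from a pattern hit set: labels inside a
#' maximal repeat hit are `"repeat"`, inside a return hit `"return"`,
#' trivial-pair labels `"plain"`, and labels in no hit at all
#' `"irreducible"` (repeat takes precedence over return when a label sits in
#' both).
#'
#' @param w A `dow`.
#' @param hits Pattern hits, by default [find_patterns()] on `w`.
#' @return A `chord_layout`: list with `n_positions` (`2 x` label count),
#'   `word` and `chords` (tibble `label`, `position_a`, `position_b`,
#'   `category`; positions are 0-based word offsets).
#' @export
chord_layout <- function(w, hits = find_patterns(w)) {
  stopifnot(inherits(w, "dow"))
  x <- as.integer(w)
  labels <- dow_labels(w)
  hit_labels <- function(kind) {
    h <- dplyr::filter(hits, .data$kind == !!kind, .data$maximal)
    if (nrow(h) == 0L) {
      return(integer(0))
    }
    unique(unlist(purrr::map2(h$start_a, h$length, function(i, L) {
      x[i:(i + L - 1L)]
    })))
  }
  rep_labels <- hit_labels("repeat")
  ret_labels <- hit_labels("return")
  triv_labels <- hit_labels("trivial_pair")
  chords <- purrr::map(labels, function(lab) {
    pos <- which(x == lab) - 1L
    category <- if (lab %in% rep_labels) {
      "repeat"
    } else if (lab %in% ret_labels) {
      "return"
    } else if (lab %in% triv_labels) {
      "plain"
    } else {
      "irreducible"
    }
    tibble::tibble(
      label = lab, position_a = pos[1L], position_b = pos[2L],
      category = category
    )
  }) |>
    dplyr::bind_rows()
  if (length(labels) == 0L) {
    chords <- tibble::tibble(
      label = integer(), position_a = integer(), position_b = integer(),
      category = character()
    )
  }
  structure(
    list(n_positions = length(x), word = w, chords = chords),
    class = "chord_layout"
  )
}

#' @export
print.chord_layout <- function(x, ...) {
  cat(
    "<chord_layout>", format(x$word), "-", x$n_positions, "positions,",
    nrow(x$chords), "chords\n"
  )
  if (nrow(x$chords)) print(x$chords)
  invisible(x)
}

#' Number of crossing chord pairs
#'
#' Two chords `(a1, a2)` and `(b1, b2)` cross iff exactly one of `b1`, `b2`
#' lies cyclically between `a1` and `a2`. The count is invariant under
#' rotation of the reference mark.
#'
#' @param layout A `chord_layout`.
#' @return Integer crossing count.
#' @export
chord_crossings <- function(layout) {
  stopifnot(inherits(layout, "chord_layout"))
  ch <- layout$chords
  n <- nrow(ch)
  if (n < 2L) {
    return(0L)
  }
  crossings <- 0L
  for (i in seq_len(n - 1L)) {
    a1 <- min(ch$position_a[i], ch$position_b[i])
    a2 <- max(ch$position_a[i], ch$position_b[i])
    for (j in seq.int(i + 1L, n)) {
      inside <- c(ch$position_a[j], ch$position_b[j]) > a1 &
        c(ch$position_a[j], ch$position_b[j]) < a2
      if (sum(inside) == 1L) crossings <- crossings + 1L
    }
  }
  crossings
}

chord_palette <- c(
  "repeat" = "#1f77b4", # blue
  "return" = "#2ca02c", # green
  "irreducible" = "#d62728", # red
  "plain" = "#7f7f7f" # gray
)

chord_xy <- function(position, n, radius, cx = 200, cy = 200) {
  theta <- -pi / 2 + 2 * pi * position / max(n, 1L) # clockwise from top
  list(x = cx + radius * cos(theta), y = cy + radius * sin(theta))
}

#' Render a chord layout as deterministic SVG
#'
#' Fixed 400x400 canvas, equally spaced positions clockwise from a radial
#' reference tick at the top, fixed palette (repeat = blue, return = green,
#' irreducible = red, plain = gray). Output is byte-identical across runs for
#' identical input. The empty word renders as the circle with the reference
#' mark only.
#'
#' @param layout A `chord_layout`.
#' @param path Output file path (`.svg`).
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, path) {
  stopifnot(inherits(layout, "chord_layout"))
  n <- layout$n_positions
  r <- 160
  fmt <- function(v) sprintf("%.3f", v)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
      "width=\"400\" height=\"400\" viewBox=\"0 0 400 400\">"
    ),
    paste0(
      "<circle cx=\"200\" cy=\"200\" r=\"", r,
      "\" fill=\"none\" stroke=\"#000000\" stroke-width=\"1\"/>"
    ),
    # reference mark: radial tick at position 0 (top)
    paste0(
      "<line x1=\"200\" y1=\"", 200 - r - 10, "\" x2=\"200\" y2=\"",
      200 - r + 10, "\" stroke=\"#000000\" stroke-width=\"2\"/>"
    )
  )
  ch <- layout$chords
  if (nrow(ch) > 0L) {
    ch <- dplyr::arrange(ch, .data$label)
    for (i in seq_len(nrow(ch))) {
      p1 <- chord_xy(ch$position_a[i], n, r)
      p2 <- chord_xy(ch$position_b[i], n, r)
      lines <- c(lines, paste0(
        "<line x1=\"", fmt(p1$x), "\" y1=\"", fmt(p1$y),
        "\" x2=\"", fmt(p2$x), "\" y2=\"", fmt(p2$y),
        "\" stroke=\"", chord_palette[[ch$category[i]]],
        "\" stroke-width=\"2\"/>"
      ))
    }
    x <- as.integer(layout$word)
    for (p in seq_len(n) - 1L) {
      v <- chord_xy(p, n, r)
      t <- chord_xy(p, n, r + 18)
      cat_p <- ch$category[ch$position_a == p | ch$position_b == p][1L]
      lines <- c(
        lines,
        paste0(
          "<circle cx=\"", fmt(v$x), "\" cy=\"", fmt(v$y),
          "\" r=\"4\" fill=\"", chord_palette[[cat_p]], "\"/>"
        ),
        paste0(
          "<text x=\"", fmt(t$x), "\" y=\"", fmt(t$y),
          "\" font-family=\"sans-serif\" font-size=\"12\" ",
          "text-anchor=\"middle\" dominant-baseline=\"middle\">",
          x[p + 1L], "</text>"
        )
      )
    }
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Plot a chord layout with ggplot2
#'
#' @param object A `chord_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chord_layout
#' @export
autoplot.chord_layout <- function(object, ...) {
  n <- object$n_positions
  ch <- object$chords
  to_xy <- function(pos) {
    theta <- -pi / 2 + 2 * pi * pos / max(n, 1L)
    data.frame(x = cos(theta), y = sin(theta))
  }
  circle <- to_xy(seq(0, max(n, 1L), length.out = 361))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = circle, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey30"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (nrow(ch) > 0L) {
    a <- to_xy(ch$position_a)
    b <- to_xy(ch$position_b)
    seg <- data.frame(
      x = a$x, y = a$y, xend = b$x, yend = b$y, category = ch$category,
      label = ch$label
    )
    lab <- to_xy(seq_len(n) - 1L)
    lab$text <- as.integer(object$word)
    p <- p +
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(
          x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          colour = .data$category
        ),
        linewidth = 0.8
      ) +
      ggplot2::geom_text(
        data = lab,
        ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
          label = .data$text
        ),
        size = 3
      ) +
      ggplot2::scale_colour_manual(values = chord_palette)
  }
  p
}
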