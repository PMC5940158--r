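# Independent oracles used by the property tests. These deliberately avoid
# the package's own search code paths.

# All repeat/return factor-pair hits (maximal or not) and trivial pairs of an
# integer vector, found by direct triple enumeration.
oracle_hits <- function(x) {
  n <- length(x)
  hits <- list()
  if (n >= 4L) {
    for (L in 2:(n %/% 2L)) {
      for (i in seq_len(n - 2L * L + 1L)) {
        for (j in seq.int(i + L, n - L + 1L)) {
          a <- x[i:(i + L - 1L)]
          b <- x[j:(j + L - 1L)]
          if (identical(a, b) || identical(a, rev(b))) {
            hits[[length(hits) + 1L]] <- c(i, j, L)
          }
        }
      }
    }
  }
  for (p in seq_len(max(n - 1L, 0L))) {
    if (x[p] == x[p + 1L]) hits[[length(hits) + 1L]] <- c(p, p + 1L, 1L)
  }
  hits
}

# Can the word reach the empty word under SOME order of removals, trying
# every hit (not only maximal ones) at every step? Memoised on the
# canonical (first-occurrence relabelled) word.
oracle_reducible <- function(w) {
  memo <- new.env(parent = emptyenv())
  rec <- function(x) {
    if (length(x) == 0L) {
      return(TRUE)
    }
    key <- paste(match(x, unique(x)), collapse = ",")
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    memo[[key]] <- FALSE # provisional
    hits <- oracle_hits(x)
    res <- FALSE
    for (h in hits) {
      nxt <- x[-c(h[1]:(h[1] + h[3] - 1L), h[2]:(h[2] + h[3] - 1L))]
      if (rec(nxt)) {
        res <- TRUE
        break
      }
    }
    memo[[key]] <- res
    res
  }
  rec(as.integer(w))
}

# Random DOW over n_labels labels (each occurring twice, shuffled).
random_dow <- function(n_labels) {
  dow(sample(rep(seq_len(n_labels), 2L)))
}

# Geometric chord-crossing oracle: place the 2m endpoints on the unit
# circle and count straight-segment intersections.
oracle_crossings <- function(layout) {
  ch <- layout$chords
  n <- layout$n_positions
  if (nrow(ch) < 2L) {
    return(0L)
  }
  xy <- function(p) {
    th <- -pi / 2 + 2 * pi * p / n
    c(cos(th), sin(th))
  }
  ccw <- function(a, b, c) {
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  }
  segments_cross <- function(p1, p2, p3, p4) {
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  }
  count <- 0L
  for (i in seq_len(nrow(ch) - 1L)) {
    for (j in seq.int(i + 1L, nrow(ch))) {
      if (segments_cross(
        xy(ch$position_a[i]), xy(ch$position_b[i]),
        xy(ch$position_a[j]), xy(ch$position_b[j])
      )) {
        count <- count + 1L
      }
    }
  }
  count
}

# MDS records realizing an arrangement on a MIC contig with fixed geometry.
records_from_arrangement <- function(map, mic_contig_id = "mic1",
                                     mds_len = 50L, ies_len = 30L) {
  n <- nrow(map$entries)
  starts <- 1L + (seq_len(n) - 1L) * (mds_len + ies_len)
  tibble::tibble(
    mic_contig_id = mic_contig_id,
    mac_contig_id = if (is.na(map$mac_contig_id)) "mac1" else map$mac_contig_id,
    mds_index = map$entries$mds_index,
    mic_start = starts,
    mic_end = starts + mds_len - 1L,
    orientation = map$entries$orientation
  )
}
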