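test_that("DOW construction validates double occurrence and serializes both dialects", {
  expect_identical(format(dow(c(1, 2, 1, 2))), "1212")
  expect_identical(format(dow()), "")
  expect_identical(
    format(dow(c(4, 10, 11, 8, 12, 11, 9, 8, 4, 9, 10, 12))),
    "4,10,11,8,12,11,9,8,4,9,10,12"
  )
  expect_error(dow(c(1, 2, 1)), "twice")
  expect_error(dow(c(0, 0)), "positive")
  expect_identical(parse_dow("12341243"), dow(c(1, 2, 3, 4, 1, 2, 4, 3)))
  expect_identical(
    parse_dow("4,10,11,8,12,11,9,8,4,9,10,12"),
    dow(c(4, 10, 11, 8, 12, 11, 9, 8, 4, 9, 10, 12))
  )
  expect_identical(parse_dow(""), dow())
  expect_error(parse_dow("102"), "0")
  # serialize/parse round trip on random words
  set.seed(3)
  for (i in 1:20) {
    w <- random_dow(sample(1:12, 1))
    expect_identical(parse_dow(format(w)), w)
  }
})

test_that("pointer words match the printed rearrangement maps", {
  cases <- list(
    c("M1 M2 M3", "1122"),
    c("M1 M3 M5 M7 -M6 -M4 -M2", "123456654321"),
    c("M1 -M2 -M3", "1212"),
    c("M2 M1 M4 M3", "121323"),
    c("M2 M3 -M8 -M7 -M1 -M4 M5 M6", "12237761434556")
  )
  for (cs in cases) {
    expect_identical(format(pointer_word(parse_arrangement(cs[1]))), cs[2])
  }
  expect_warning(w1 <- pointer_word(parse_arrangement("M1")), "single MDS")
  expect_length(w1, 0)
})

test_that("identity and whole-inverted maps give fully trivial words for all k <= 8", {
  for (k in 2:8) {
    ident <- parse_arrangement(paste0("M", 1:k, collapse = " "))
    w <- pointer_word(ident)
    expect_identical(as.integer(w), rep(1:(k - 1), each = 2))
    expect_length(strip_trivial_pairs(w)$word, 0)
    inv <- parse_arrangement(paste0("-M", k:1, collapse = " "))
    expect_length(strip_trivial_pairs(pointer_word(inv))$word, 0)
    expect_false(is_scrambled(ident))
    expect_false(is_scrambled(inv))
  }
})

test_that("nonscrambled random maps always strip to the empty word", {
  set.seed(7)
  for (rep in 1:100) {
    k <- sample(2:10, 1)
    map <- parse_arrangement(paste0(
      ifelse(runif(k) < 0.5, "-", ""), "M", sample(k),
      collapse = " "
    ))
    if (!is_scrambled(map)) {
      expect_length(strip_trivial_pairs(pointer_word(map))$word, 0)
    }
  }
})

test_that("terminal MDS orientation does not change the pointer word", {
  set.seed(5)
  for (rep in 1:30) {
    k <- sample(3:9, 1)
    perm <- sample(k)
    ori <- runif(k) < 0.5
    tok <- function(flip_idx = NULL) {
      o <- ori
      if (!is.null(flip_idx)) o[perm == flip_idx] <- !o[perm == flip_idx]
      paste0(ifelse(o, "-", ""), "M", perm, collapse = " ")
    }
    base <- pointer_word(parse_arrangement(tok()))
    expect_identical(pointer_word(parse_arrangement(tok(1L))), base)
    expect_identical(pointer_word(parse_arrangement(tok(k))), base)
  }
})

test_that("trivial-pair stripping cascades and counts conventional IESs", {
  st <- strip_trivial_pairs(parse_dow("1122"))
  expect_length(st$word, 0)
  expect_identical(st$removed, 2L)
  st8 <- strip_trivial_pairs(
    pointer_word(parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6"))
  )
  expect_identical(format(st8$word), "13614346")
  expect_identical(st8$removed, 3L)
  expect_identical(strip_trivial_pairs(parse_dow("1212"))$removed, 0L)
  # cascade: removing the inner pair exposes the outer one
  casc <- strip_trivial_pairs(dow(c(1, 2, 2, 1)))
  expect_length(casc$word, 0)
  expect_identical(casc$removed, 2L)
})

test_that("rank renumbering compresses labels preserving numeric order", {
  expect_identical(
    format(renumber_by_rank(dow(c(1, 3, 6, 1, 4, 3, 4, 6)))),
    "12413234"
  )
  expect_identical(renumber_by_rank(dow()), dow())
  expect_identical(format(renumber_by_rank(dow(c(5, 5)))), "11")
})

test_that("merging consecutive MDSs and renumbering agree on the 8-MDS locus", {
  lhs <- renumber_by_rank(
    strip_trivial_pairs(
      pointer_word(parse_arrangement("M2 M3 -M8 -M7 -M1 -M4 M5 M6"))
    )$word
  )
  rhs <- pointer_word(parse_arrangement("M2 -M5 -M1 -M3 M4"))
  expect_identical(lhs, rhs)
})

test_that("scrambled pointer count and isomorphism behave canonically", {
  expect_identical(
    scrambled_pointer_count(parse_dow("4,10,11,8,12,11,9,8,4,9,10,12")), 6L
  )
  expect_identical(scrambled_pointer_count(parse_dow("12413234")), 4L)
  expect_identical(scrambled_pointer_count(dow()), 0L)
  expect_true(dow_isomorphic(parse_dow("1313"), parse_dow("1212")))
  expect_false(dow_isomorphic(parse_dow("1212"), parse_dow("1122")))
  # relabeling invariance on random words
  set.seed(13)
  for (i in 1:20) {
    w <- random_dow(5)
    relabeled <- dow(match(as.integer(w), unique(as.integer(w))) * 3L)
    expect_true(dow_isomorphic(w, relabeled))
  }
})
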