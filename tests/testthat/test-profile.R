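test_that("profiles assign the per-class index position by position", {
  expect_identical(profile_sequence("GGGGG")$values, rep(-2L, 5))
  p <- profile_sequence("GTW")
  expect_identical(p$values, c(-2L, -1L, 2L))
  expect_identical(p$classes, c("high", "moderate", "weak"))
  expect_true(all(p$values %in% c(-2L, -1L, 2L)))
})

test_that("unknown-residue policies behave as documented", {
  expect_warning(p <- profile_sequence("GXW", unknown_policy = "skip"),
                 "skipped")
  expect_identical(p$values, c(-2L, 2L))
  expect_identical(p$skipped, 1L)
  expect_identical(p$positions, c(1L, 3L))  # original numbering retained

  z <- profile_sequence("GXW", unknown_policy = "zero")
  expect_identical(z$values, c(-2L, 0L, 2L))
  expect_true(is.na(z$classes[2]))
  expect_identical(z$skipped, 0L)

  expect_error(profile_sequence("GXW", unknown_policy = "error"),
               "position\\(s\\) 2")
})

test_that("profile length bookkeeping holds across policies", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_aa_sequence(sample(1:120, 1),
                            alphabet = c(names(TABLE1_CLASS), "X", "B"))
    n <- nchar(s)
    expect_identical(length(profile_sequence(s, unknown_policy = "zero")$values),
                     n)
    p <- suppressWarnings(profile_sequence(s, unknown_policy = "skip"))
    expect_identical(length(p$values) + p$skipped, n)
  }
})

test_that("smoothing is a centered mean with symmetric end shrinkage", {
  p <- profile_sequence("GTW")
  expect_identical(smooth_profile(p, 1)$smoothed, as.numeric(p$values))
  s3 <- smooth_profile(p, 3)$smoothed
  expect_equal(s3, c(-2, (-2 - 1 + 2) / 3, 2))
  # constant profile stays constant under any valid window
  q <- profile_sequence(strrep("G", 11))
  for (w in c(1, 3, 5, 11))
    expect_equal(smooth_profile(q, w)$smoothed, rep(-2, 11))
  expect_error(smooth_profile(p, 2), "odd")
  expect_error(smooth_profile(p, 0), "odd")
  expect_error(smooth_profile(p, 5), "exceeds")
})

test_that("smoothed values stay within the raw range", {
  set.seed(7)
  for (i in 1:15) {
    p <- profile_sequence(random_aa_sequence(sample(5:150, 1)))
    w <- sample(seq(1, min(11, length(p$values)), by = 2), 1)
    sm <- smooth_profile(p, w)$smoothed
    expect_true(all(sm >= min(p$values) - 1e-12 &
                    sm <= max(p$values) + 1e-12))
  }
})

test_that("composition matches a per-letter tally and the documented examples", {
  expect_equal(composition("GASPD")$fractions,
               c(high = 1, moderate = 0, weak = 0))
  expect_equal(composition("GW")$fractions,
               c(high = 0.5, moderate = 0, weak = 0.5))
  cro <- load_fixture("crotamine")
  got <- composition(list(cro))
  want <- oracle_composition(cro$residues)
  expect_identical(unname(got$counts), unname(want$counts))
  expect_equal(unname(got$fractions), unname(want$fractions))
  expect_identical(got$total, 42L)
  expect_equal(sum(got$fractions), 1)
  expect_error(composition("XXX"), "no classifiable")
})

test_that("composition is permutation-invariant and pools additively", {
  set.seed(23)
  seqs <- vapply(1:6, function(i) random_aa_sequence(sample(10:80, 1)),
                 character(1))
  pooled <- composition(seqs)
  # permuting residues within and across records changes nothing
  shuffled <- paste(sample(unlist(strsplit(seqs, ""))), collapse = "")
  expect_identical(pooled$counts, composition(shuffled)$counts)
  # pooled counts are the sums of the parts
  a <- composition(seqs[1:2]); b <- composition(seqs[3:6])
  expect_identical(pooled$counts, a$counts + b$counts)
  expect_equal(sum(pooled$fractions), 1)
})

test_that("segment calling reproduces the documented boundary cases", {
  allw <- profile_sequence(strrep("W", 40))
  expect_identical(nrow(call_segments(allw, threshold = -1, min_length = 1)), 0L)

  g35 <- call_segments(profile_sequence(strrep("G", 35)),
                       threshold = -1, min_length = 30)
  expect_identical(g35$start, 1L)
  expect_identical(g35$end, 35L)
  expect_equal(g35$mean_index, -2)

  split <- profile_sequence(paste0(strrep("G", 20), strrep("W", 5),
                                   strrep("G", 20)))
  expect_identical(nrow(call_segments(split, -1, 30)), 0L)
  two <- call_segments(split, -1, 20)
  expect_identical(two$start, c(1L, 26L))
  expect_identical(two$end, c(20L, 45L))
})

test_that("segment calling equals a brute-force run scan on random profiles", {
  set.seed(99)
  for (i in 1:40) {
    p <- profile_sequence(random_aa_sequence(sample(1:200, 1)))
    if (runif(1) < 0.5 && length(p$values) >= 3)
      p <- smooth_profile(p, sample(seq(3, min(9, length(p$values)), 2), 1))
    thr <- sample(c(-2, -1.5, -1, 0, 1), 1)
    ml <- sample(1:30, 1)
    got <- call_segments(p, thr, ml)
    v <- if (is.null(p$smoothed)) as.numeric(p$values) else p$smoothed
    want <- oracle_segments(v, thr, ml)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, unname(as.integer(want[, "start"])))
      expect_identical(got$end, unname(as.integer(want[, "end"])))
      expect_identical(got$length, unname(as.integer(want[, "length"])))
    }
  }
})

test_that("segments are called on the smoothed series when present", {
  p <- profile_sequence("GGWGG")          # raw: -2 -2 2 -2 -2
  raw <- call_segments(p, -0.5, 1)
  expect_identical(nrow(raw), 2L)         # the W breaks the raw run
  # smoothed (window 5): -2, -2/3, -1.2, -2/3, -2 — all at or below -0.5
  sm <- smooth_profile(p, 5)
  one <- call_segments(sm, -0.5, 5)
  expect_identical(nrow(one), 1L)
  expect_identical(one$length, 5L)
})

test_that("agreement reproduces a position-by-position confusion matrix", {
  p <- profile_sequence(paste0(strrep("G", 10), strrep("W", 10)))
  segs <- call_segments(p, -1, 5)
  ref <- c(rep(TRUE, 10), rep(FALSE, 10))
  rep_ <- agreement(segs, ref, 20)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)

  none <- agreement(segs[0, ], rep(TRUE, 20), 20)
  expect_equal(none$sensitivity, 0)
  expect_identical(none$fn, 20L)

  set.seed(5)
  for (i in 1:10) {
    prof <- profile_sequence(random_aa_sequence(50))
    sg <- call_segments(prof, -1, sample(1:10, 1))
    ref <- runif(50) < 0.4
    got <- agreement(sg, ref, 50)
    pred <- rep(FALSE, 50)
    for (k in seq_len(nrow(sg))) pred[sg$start[k]:sg$end[k]] <- TRUE
    want <- oracle_confusion(pred, ref)
    expect_identical(c(tp = got$tp, fp = got$fp, tn = got$tn, fn = got$fn),
                     want)
    expect_identical(got$tp + got$fp + got$tn + got$fn, 50L)
  }
  expect_error(agreement(data.frame(start = 1L, end = 60L), rep(TRUE, 50), 50),
               "out of range")
})
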