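# ignore-label target generation at three resolutions

test_that("two-beat example matches the analytic label regions", {
  # beats at 1.0 s and 2.0 s, l = 750 @ 250 Hz (3 s)
  tg <- make_targets(c(250L, 500L), 750L, fs = 250)
  lab <- tg$labels[[1]]
  t <- (0:749) / 250
  # positives: within 75 ms of either beat (edge mask cannot reach them)
  expect_true(all(lab[abs(t - 1) < 0.075 | abs(t - 2) < 0.075] == 1L))
  # negatives: strictly between the beats and > 150 ms from both
  expect_true(all(lab[t > 1.15 & t < 1.85] == 0L))
  # border zone between positive and negative is ignored
  expect_true(all(lab[t >= 1.075 & t <= 1.15] == -1L))
  expect_true(all(lab[t >= 1.85 & t <= 1.925] == -1L))
  # outside the annotated span (and beyond 75 ms of the end beats): ignored
  expect_true(all(lab[t < 1 - 0.075] == -1L))
  expect_true(all(lab[t > 2 + 0.075] == -1L))
})

test_that("an interior on-grid beat gets exactly 37 positive samples", {
  # |i/250 - t| < 0.075 <=> i in (t*250 - 18.75, t*250 + 18.75): 37 integers
  tg <- make_targets(c(250L, 500L, 750L), 1250L, fs = 250)
  lab <- tg$labels[[1]]
  i <- 0:1249
  expect_equal(sum(lab[abs(i - 500) <= 19] == 1L), 37L)
})

test_that("single-beat targets keep only the positive neighbourhood", {
  tg <- make_targets(500L, 1000L, fs = 250)
  lab <- tg$labels[[1]]
  i <- 0:999
  d <- abs(i - 500) / 250
  expect_true(all(lab[d < 0.075] == 1L))
  expect_true(all(lab[d >= 0.075] == -1L))
  expect_true(all(lab != 0L))
})

test_that("no annotations gives an all-ignore target", {
  tg <- make_targets(integer(0), 600L)
  for (i in 1:3) expect_true(all(tg$labels[[i]] == -1L))
})

test_that("the 200 ms edges are forced to ignore at every resolution", {
  tg <- make_targets(c(30L, 100L, 970L), 1000L, fs = 250)
  edge_n <- c(50L, 25L, 13L)   # round(0.2 * 250 / r), half away from zero
  for (i in 1:3) {
    lab <- tg$labels[[i]]
    expect_true(all(lab[seq_len(edge_n[i])] == -1L))
    expect_true(all(lab[(length(lab) - edge_n[i] + 1L):length(lab)] == -1L))
  }
})

test_that("vectorized targets equal the brute-force oracle on random sets", {
  set.seed(123)
  for (rep in 1:200) {
    l <- sample(300:2000, 1)
    m <- sample(0:12, 1)
    ann <- sort(sample(0:(l - 1), m))
    tg <- make_targets(ann, l, fs = 250)
    orc <- oracle_targets(ann, l, fs = 250)
    for (i in 1:3) expect_identical(tg$labels[[i]], orc[[i]])
  }
})

test_that("label invariants hold: nesting and value domain", {
  set.seed(7)
  for (rep in 1:20) {
    l <- 2500L
    ann <- sort(sample(100:2400, 8))
    tg <- make_targets(ann, l)
    for (i in 1:3) {
      r <- c(1, 2, 4)[i]
      lab <- tg$labels[[i]]
      expect_true(all(lab %in% c(-1L, 0L, 1L)))
      t <- (seq_along(lab) - 1) * r / 250
      d <- vapply(t, function(x) min(abs(x - ann / 250)), numeric(1))
      expect_true(all(d[lab == 1L] < 0.075))
      expect_true(all(d[lab == 0L] > 0.150))
    }
    # every interior beat keeps at least one positive full-res sample
    interior <- ann[ann / 250 > 0.275 & ann / 250 < (l / 250 - 0.275)]
    for (a in interior) {
      expect_true(any(tg$labels[[1]][max(1, a - 18):(a + 19)] == 1L))
    }
  }
})

test_that("unsorted or out-of-range annotations are rejected", {
  expect_error(make_targets(c(500L, 100L), 1000L), "sorted")
  expect_error(make_targets(c(100L, 1000L), 1000L), "\\[0, l\\)")
})
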