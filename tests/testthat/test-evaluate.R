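# beat matching, Sen/Pre/Err, per-type Fnr, margins

test_that("matching handles the documented mixed example", {
  fs <- 100
  ann <- c(100L, 200L, 300L)            # 1.0, 2.0, 3.0 s
  det <- c(105L, 250L)                  # 1.05, 2.5 s
  m <- match_beats(det, ann, fs = fs, tol_s = 0.15)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$det, 105L)
  expect_equal(m$pairs$ann, 100L)
  expect_equal(m$fp, 250L)              # 0.5 s from both neighbours
  expect_equal(m$fn, c(200L, 300L))
})

test_that("identical lists match perfectly with zero margins", {
  ann <- c(100L, 300L, 500L)
  m <- match_beats(ann, ann, fs = 250)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$fp, 0L)
  expect_length(m$fn, 0L)
  ms <- margin_stats(m$pairs)
  expect_equal(ms$mean_ms, 0)
  expect_equal(ms$sd_ms, 0)
})

test_that("one annotation absorbs at most one detection", {
  m <- match_beats(c(95L, 105L), 100L, fs = 250, tol_s = 0.15)
  expect_equal(nrow(m$pairs), 1L)
  expect_length(m$fp, 1L)
  expect_length(m$fn, 0L)
})

test_that("matching equals the brute-force nearest-assignment oracle", {
  set.seed(77)
  for (rep in 1:500) {
    fs <- 250
    na <- sample(0:20, 1)
    nd <- sample(0:20, 1)
    ann <- sort(sample(seq(0L, 5000L, by = 7L), na))   # step 7 avoids ties
    det <- sort(sample(seq(3L, 5000L, by = 11L), nd))
    got <- match_beats(det, ann, fs = fs, tol_s = 0.15)
    want <- oracle_match(det, ann, fs = fs, tol_s = 0.15)
    expect_equal(nrow(got$pairs), want$tp)
    expect_length(got$fp, want$fp)
    expect_length(got$fn, want$fn)
    # conservation: tp + fn = beats, tp + fp = detections
    expect_equal(nrow(got$pairs) + length(got$fn), na)
    expect_equal(nrow(got$pairs) + length(got$fp), nd)
  }
})

test_that("metric formulas reproduce published count triples", {
  r1 <- qrs_metrics(50803, 208, 218)
  expect_equal(round(r1$sen, 2), 99.57)
  expect_equal(round(r1$pre, 2), 99.59)
  expect_equal(round(r1$err, 2), 0.83)
  r2 <- qrs_metrics(24253, 1466, 1337)
  expect_equal(round(r2$sen, 2), 94.78)
  expect_equal(round(r2$pre, 2), 94.30)
  expect_equal(round(r2$err, 2), 10.36)
  r3 <- qrs_metrics(1, 0, 0)
  expect_equal(c(r3$sen, r3$pre, r3$err), c(100, 100, 0))
  # degenerate denominators flag NA instead of crashing
  r0 <- qrs_metrics(0, 0, 0)
  expect_true(all(is.na(c(r0$sen, r0$pre, r0$err))))
})

test_that("per-type false-negative rates cover present types only", {
  ann <- tibble::tibble(sample = c(100L, 300L, 500L, 700L),
                        symbol = c("N", "V", "V", "N"),
                        aami = c("N", "V", "V", "N"))
  fnr <- fnr_by_type(500L, ann)          # one of two V beats missed
  expect_equal(sort(fnr$aami), c("N", "V"))
  expect_equal(fnr$fnr[fnr$aami == "V"], 50)
  expect_equal(fnr$fnr[fnr$aami == "N"], 0)
  expect_false("S" %in% fnr$aami)
})

test_that("margin statistics use absolute offsets and sample sd", {
  pairs <- tibble::tibble(det = c(10L, 20L, 30L), ann = c(12L, 25L, 36L),
                          dt_s = c(-0.010, -0.020, -0.030))
  ms <- margin_stats(pairs)
  expect_equal(ms$mean_ms, 20)
  expect_equal(ms$sd_ms, stats::sd(c(10, 20, 30)))
  single <- margin_stats(pairs[1, ])
  expect_equal(single$sd_ms, 0)
})

test_that("evaluate_detections assembles a full report with tidiers", {
  rec <- simulate_segment(sim_config(duration_s = 20, bpm = 90, snr_db = 20,
                                     seed = 12))
  det <- qrspeak:::new_detections(rec$annotations$sample,
                                  rep(0.9, nrow(rec$annotations)),
                                  fs = 250, record_id = rec$record_id)
  ev <- evaluate_detections(det, rec)
  expect_s3_class(ev, "qrs_eval")
  expect_equal(ev$counts$tp, nrow(rec$annotations))
  expect_equal(ev$counts$sen, 100)
  gl <- glance(ev)
  expect_equal(gl$tp + gl$fn, ev$n_beats)
  expect_equal(gl$tolerance_s, 0.15)
  td <- tidy(ev)
  expect_true("N" %in% td$aami)
  # the stricter tolerance convention is honoured
  off <- qrspeak:::new_detections(rec$annotations$sample + 25L,
                                  rep(0.9, nrow(rec$annotations)),
                                  fs = 250)
  ev_tight <- evaluate_detections(off, rec, tol_s = 0.075)
  expect_equal(ev_tight$counts$fp, nrow(rec$annotations))  # 100 ms > 75 ms
  ev_loose <- evaluate_detections(off, rec, tol_s = 0.15)
  expect_equal(ev_loose$counts$tp, nrow(rec$annotations))
})

test_that("aggregation pools counts across records", {
  recs <- lapply(c(21, 22), function(s)
    simulate_segment(sim_config(duration_s = 20, bpm = 60, snr_db = 20,
                                seed = s)))
  evs <- lapply(recs, function(r) {
    det <- qrspeak:::new_detections(r$annotations$sample,
                                    rep(0.9, nrow(r$annotations)), fs = 250)
    evaluate_detections(det, r)
  })
  agg <- aggregate_evals(evs)
  expect_equal(agg$counts$tp, sum(vapply(evs, function(e) e$counts$tp,
                                         numeric(1))))
  expect_equal(agg$counts$sen, 100)
})
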