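# masked loss, segment slicing, optimization loop

test_that("masked BCE is ln 2 for uniform 0.5 predictions, any mask", {
  set.seed(1)
  for (rep in 1:5) {
    l <- 600L
    ann <- sort(sample(150:450, 3))
    tg <- make_targets(ann, l)
    maps <- lapply(tg$labels, function(lab) rep(0.5, length(lab)))
    expect_equal(masked_bce(maps, tg), log(2), tolerance = 1e-9)
  }
})

test_that("masked BCE vanishes at perfect prediction", {
  tg <- make_targets(c(200L, 400L), 800L)
  maps <- lapply(tg$labels, function(lab) {
    p <- ifelse(lab == 1L, 1, 0)
    pmin(pmax(p, 1e-7), 1 - 1e-7)
  })
  expect_lte(masked_bce(maps, tg), 1.2e-6)
})

test_that("the loss ignores predictions at -1 positions but not labels", {
  set.seed(2)
  tg <- make_targets(c(200L, 400L), 800L)
  maps <- lapply(tg$labels, function(lab) stats::runif(length(lab), 0.1, 0.9))
  base <- masked_bce(maps, tg)
  # perturb predictions only where ignored: loss unchanged
  maps2 <- maps
  for (i in 1:3) {
    ign <- tg$labels[[i]] == -1L
    maps2[[i]][ign] <- stats::runif(sum(ign), 0.1, 0.9)
  }
  expect_identical(masked_bce(maps2, tg), base)
  # flip some ignored labels to valid values: loss changes
  tg2 <- tg
  ign1 <- which(tg$labels[[1]] == -1L)
  tg2$labels[[1]][ign1[1:20]] <- 0L
  expect_false(isTRUE(all.equal(masked_bce(maps, tg2), base)))
  # fully masked targets are rejected
  tg_empty <- make_targets(integer(0), 800L)
  expect_error(masked_bce(maps, tg_empty), "fully masked")
})

test_that("segment slicing drops partial windows and conserves beats", {
  rec <- simulate_segment(sim_config(duration_s = 70, bpm = 60, snr_db = 20,
                                     seed = 3))
  segs <- slice_segments(rec, seg_s = 60)
  expect_length(segs, 1L)
  expect_equal(nrow(segs[[1]]$signal), 15000L)
  # 30-minute record at 250 Hz -> 30 windows of 15000 samples
  long <- simulate_segment(sim_config(duration_s = 1800, bpm = 70,
                                      snr_db = 20, seed = 4))
  segs30 <- slice_segments(long, seg_s = 60)
  expect_length(segs30, 30L)
  expect_true(all(vapply(segs30, function(s) nrow(s$signal), integer(1)) ==
                    15000L))
  in_windows <- sum(long$annotations$sample < 30L * 15000L)
  expect_equal(sum(vapply(segs30, function(s) nrow(s$annotations),
                          integer(1))), in_windows)
  # window-local indices stay in range
  expect_true(all(vapply(segs30, function(s)
    all(s$annotations$sample >= 0 & s$annotations$sample < 15000L),
    logical(1))))
})

test_that("epochs = 0 returns the initial weights unchanged", {
  recs <- simulate_corpus(2, duration_s = 20, seed = 5)
  m <- build_model(tiny_model_config(), seed = 5)
  fit <- fit_qrs(m, recs[1], recs[2], epochs = 0L, seg_s = 10, seed = 1)
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is reproducible and reduces the validation loss", {
  recs <- simulate_corpus(8, duration_s = 30, seed = 6)
  m <- build_model(tiny_model_config(), seed = 6)
  init_val <- mean(vapply(recs[7:8], function(r) {
    canon <- preprocess_record(r)
    masked_bce(forward(m, canon$signal),
               make_targets(canon$annotations$sample, nrow(canon$signal)))
  }, numeric(1)))
  f1 <- fit_qrs(m, recs[1:6], recs[7:8], epochs = 2L, batch_size = 4L,
                seg_s = 15, seed = 11)
  f2 <- fit_qrs(m, recs[1:6], recs[7:8], epochs = 2L, batch_size = 4L,
                seg_s = 15, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  best_val <- f1$history$val_loss[f1$best_epoch]
  expect_lt(best_val, init_val)
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
})

test_that("fit tidiers expose history and summary", {
  recs <- simulate_corpus(3, duration_s = 20, seed = 7)
  m <- build_model(tiny_model_config(), seed = 7)
  fit <- fit_qrs(m, recs[1:2], recs[3], epochs = 1L, batch_size = 2L,
                 seg_s = 10, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  gl <- glance(fit)
  expect_equal(gl$epochs, 1L)
  expect_equal(gl$n_parameters, count_parameters(fit$model))
})
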