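# synthetic ECG segments and the three noise processes

test_that("beat count equals round(bpm * duration / 60) and is annotated", {
  rec <- simulate_segment(sim_config(bpm = 240, duration_s = 10, seed = 1))
  expect_equal(nrow(rec$annotations), 40L)
  set.seed(99)
  for (i in 1:20) {
    bpm <- stats::runif(1, 40, 280)
    dur <- stats::runif(1, 5, 30)
    if (bpm * dur / 60 < 1) next
    rec <- simulate_segment(sim_config(bpm = bpm, duration_s = dur,
                                       snr_db = 10, seed = i))
    expect_equal(nrow(rec$annotations), round(bpm * dur / 60))
  }
})

test_that("annotations sit on the rendered R peaks in the noise-free limit", {
  rec <- simulate_segment(sim_config(bpm = 240, duration_s = 10,
                                     snr_db = Inf, seed = 2))
  for (s in rec$annotations$sample) {
    win <- max(1, s - 10):min(nrow(rec$signal), s + 12)
    local_max <- win[which.max(rec$signal[win, 1])] - 1L
    expect_lte(abs(local_max - s), 1L)
  }
})

test_that("realized white-noise SNR matches the request", {
  for (snr in c(0, 6, 12)) {
    cfg <- sim_config(bpm = 240, duration_s = 10, snr_db = snr, seed = 3)
    clean <- simulate_segment(sim_config(bpm = 240, duration_s = 10,
                                         snr_db = Inf, seed = 3))
    noisy <- simulate_segment(cfg)
    resid <- noisy$signal - clean$signal
    measured <- 10 * log10(mean(clean$signal^2) / mean(resid^2))
    expect_lt(abs(measured - snr), 0.1)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_segment(sim_config(seed = 11))
  b <- simulate_segment(sim_config(seed = 11))
  expect_identical(a$signal, b$signal)
  expect_identical(a$annotations, b$annotations)
})

test_that("baseline-wander frequencies follow the three-Gaussian mixture", {
  set.seed(17)
  f <- qrspeak:::draw_bw_frequency(10000)
  expect_true(all(f > 0))
  # mixture mean (0.05 + 0.15 + 0.25)/3 = 0.15, slightly shifted by the
  # positivity rejection; empirical mean must sit in 0.15 +- 0.01
  expect_lt(abs(mean(f) - 0.15), 0.01)
  bw <- gen_baseline_wander(1000, fs = 250, amp_z = 0, seed = 1)
  expect_equal(bw, rep(0, 1000))
  expect_identical(gen_baseline_wander(500, 250, 1, seed = 4),
                   gen_baseline_wander(500, 250, 1, seed = 4))
})

test_that("muscle artifact is standard white noise", {
  ma <- gen_muscle_artifact(10000, seed = 5)
  expect_lt(abs(mean(ma)), 0.05)
  expect_lt(abs(stats::sd(ma) - 1), 0.05)
  expect_identical(ma, gen_muscle_artifact(10000, seed = 5))
})

test_that("electrode motion is band-limited to 5-15 Hz", {
  n <- 25000; fs <- 250
  em <- gen_electrode_motion(n, fs, seed = 6)
  expect_length(em, n)
  spec <- Mod(stats::fft(em))[1:(n %/% 2)]^2
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  frac_out <- sum(spec[freq < 2 | freq > 25]) / sum(spec)
  expect_lt(frac_out, 0.10)
})

test_that("SNR mixing has the exact closed-form scale", {
  set.seed(7)
  clean <- stats::rnorm(5000)
  clean <- clean / sqrt(mean(clean^2))        # unit power
  noise <- stats::rnorm(5000)
  noise <- noise / sqrt(mean(noise^2))
  y0 <- mix_at_snr(clean, noise, 0)
  expect_equal(y0, clean + noise, tolerance = 1e-12)
  y20 <- mix_at_snr(clean, noise, 20)
  expect_equal(y20, clean + 0.1 * noise, tolerance = 1e-12)
  resid <- y20 - clean
  expect_lt(abs(10 * log10(mean(clean^2) / mean(resid^2)) - 20), 1e-9)
  expect_error(mix_at_snr(clean, rep(0, 5000), 6), "zero power")
})

test_that("flip/swap augmentation is an involution", {
  set.seed(8)
  x <- matrix(stats::rnorm(200), ncol = 2)
  expect_equal(augment_channels(x, flip = c(TRUE, FALSE))[, 1], -x[, 1])
  expect_equal(augment_channels(x, swap = TRUE), x[, c(2, 1)])
  # double application is the identity whenever flip and swap commute
  # (no swap, or a symmetric flip mask)
  cases <- list(list(c(TRUE, FALSE), FALSE), list(c(FALSE, TRUE), FALSE),
                list(c(TRUE, TRUE), TRUE), list(c(FALSE, FALSE), TRUE),
                list(c(TRUE, TRUE), FALSE))
  for (cs in cases) {
    y <- augment_channels(augment_channels(x, cs[[1]], cs[[2]]),
                          cs[[1]], cs[[2]])
    expect_equal(y, x, ignore_attr = TRUE)
  }
})
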