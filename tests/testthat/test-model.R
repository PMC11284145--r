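# model construction, parameter accounting, forward contracts

test_that("default model has exactly 26,976 trainable parameters", {
  m <- build_model(qrs_model_config(), seed = 1)
  expect_identical(count_parameters(m), 26976L)
  # counting twice changes nothing
  expect_identical(count_parameters(m), 26976L)
})

test_that("single-channel variant differs only by the stem input weights", {
  m2 <- build_model(qrs_model_config(), seed = 1)
  m1 <- build_model(qrs_model_config(in_channels = 1L), seed = 1)
  expect_identical(count_parameters(m2) - count_parameters(m1),
                   19L * 32L)   # one 19-tap dense stem column set
})

test_that("ablation kernel sizes build and run", {
  for (k in c(9L, 29L)) {
    m <- build_model(qrs_model_config(kernel_size = k), seed = 2)
    hm <- forward(m, matrix(stats::rnorm(400 * 2), 400, 2))
    expect_true(all(vapply(hm$maps, function(x) all(x >= 0 & x <= 1),
                           logical(1))))
  }
  m1 <- build_model(qrs_model_config(in_channels = 1L), seed = 2)
  hm <- forward(m1, matrix(stats::rnorm(400), 400, 1))
  expect_length(hm$maps[[1]], 400L)
})

test_that("forward yields three bounded maps at l, l/2, l/4", {
  m <- build_model(seed = 3)
  hm <- forward(m, matrix(0, 1000, 2))
  expect_equal(vapply(hm$maps, length, integer(1)), c(1000L, 500L, 250L))
  for (i in 1:3) {
    expect_true(all(is.finite(hm$maps[[i]])))
    expect_true(all(hm$maps[[i]] >= 0 & hm$maps[[i]] <= 1))
  }
  expect_equal(hm$fs_per_map, c(250, 125, 62.5))
})

test_that("odd input lengths are padded internally and cropped back", {
  m <- build_model(tiny_model_config(), seed = 4)
  hm <- forward(m, matrix(stats::rnorm(1001 * 2), 1001, 2))
  expect_equal(vapply(hm$maps, length, integer(1)),
               c(1001L, ceiling(1001 / 2), ceiling(1001 / 4)))
  expect_error(forward(m, matrix(0, 16, 2)), "minimum length")
})

test_that("the detector is translation-covariant away from borders", {
  # covariance is exact for the convolutional path; the only residual
  # coupling is through the global instance-norm statistics, whose
  # edge-induced perturbation scales as O(RF / n)
  m <- build_model(tiny_model_config(), seed = 5)
  set.seed(5)
  shift_err <- function(n, shift = 4L) {
    x <- matrix(stats::rnorm(n * 2), n, 2)
    xs <- rbind(x[(shift + 1):n, ], x[1:shift, ])   # circular shift
    a <- forward(m, x)$maps[[1]]
    b <- forward(m, xs)$maps[[1]]
    interior <- 200:(n - 200)
    max(abs(a[interior + shift] - b[interior]))
  }
  e1 <- shift_err(3200L)
  expect_lt(e1, 1e-3)
  # the instance-norm coupling decays with input length
  e2 <- shift_err(12800L)
  expect_lt(e2, e1 / 2)
})

test_that("inference is deterministic", {
  m <- build_model(tiny_model_config(), seed = 6)
  x <- matrix(stats::rnorm(500 * 2), 500, 2)
  expect_identical(forward(m, x)$maps, forward(m, x)$maps)
})

test_that("receptive field is about 2 s and monotone in kernel size", {
  rf <- receptive_field_s(qrs_model_config())
  expect_gte(rf, 1.5)
  expect_lte(rf, 2.5)
  expect_lt(receptive_field_s(qrs_model_config(kernel_size = 9L)), rf)
  expect_gt(receptive_field_s(qrs_model_config(kernel_size = 29L)), rf)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_model_config(), seed = 7)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, m$params)
  x <- matrix(stats::rnorm(200 * 2), 200, 2)
  expect_identical(forward(back, x)$maps, forward(m, x)$maps)
})

test_that("analytic gradients match central differences on a tiny model", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 8)
  set.seed(8)
  x <- matrix(stats::rnorm(256 * 2), 256, 2)
  tg <- make_targets(c(80L, 130L, 180L), 256L)
  out <- qrspeak:::nn_forward(m$params, cfg, x, training = TRUE)
  lg <- qrspeak:::masked_bce_grad(out$maps, tg)
  G <- qrspeak:::nn_backward(m$params, cfg, out$cache, lg$dmaps)
  eps <- 1e-6
  loss_at <- function(p) {
    qrspeak:::masked_bce_grad(qrspeak:::nn_forward(p, cfg, x, TRUE)$maps,
                              tg, want_grad = FALSE)$loss
  }
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(3L, length(m$params[[nm]])))
    for (ii in idx) {
      pp <- m$params
      pp[[nm]][ii] <- pp[[nm]][ii] + eps
      up <- loss_at(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps
      dn <- loss_at(pp)
      num <- (up - dn) / (2 * eps)
      ana <- G[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})
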