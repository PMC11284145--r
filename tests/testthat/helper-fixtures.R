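# shared fixtures: tiny records and models built in code

# a desk-width model trained once per session on a small synthetic corpus,
# reused by the detection and CLI integration tests
.fixture_env <- new.env(parent = emptyenv())
desk_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    recs <- simulate_corpus(10, duration_s = 30, seed = 31)
    m <- build_model(model_preset("desk"), seed = 31)
    .fixture_env$fit <- fit_qrs(m, recs[1:8], recs[9:10], epochs = 2L,
                                batch_size = 4L, seg_s = 15, seed = 31)
  }
  .fixture_env$fit
}

tiny_record <- function(n = 2500, fs = 250, n_leads = 2, beats = c(500L, 1000L, 1500L),
                        seed = 42) {
  set.seed(seed)
  sig <- matrix(stats::rnorm(n * n_leads, sd = 0.1), n, n_leads)
  for (b in beats) sig[b + 1L, ] <- sig[b + 1L, ] + 2
  ecg_record(sig, fs = fs,
             annotations = tibble::tibble(sample = beats, symbol = "N"),
             record_id = "tiny")
}

tiny_model_config <- function() {
  qrs_model_config(kernel_size = 5L, channels = c(3L, 4L, 6L),
                   fpn_channels = 3L, head_kernel = 3L, pool_size = 3L)
}

# brute-force per-sample target oracle: O(n * m) distance loop with the
# same label semantics as make_targets, written independently
oracle_targets <- function(annotations, l, fs = 250) {
  t_ann <- annotations / fs
  lapply(c(1, 2, 4), function(r) {
    len <- ceiling(l / r)
    lab <- rep(-1L, len)
    if (length(t_ann) > 0) {
      for (i in seq_len(len)) {
        t_i <- (i - 1) * r / fs
        d <- min(abs(t_i - t_ann))
        if (d < 0.075) {
          lab[i] <- 1L
        } else if (t_i > t_ann[1] && t_i < t_ann[length(t_ann)] && d > 0.150) {
          lab[i] <- 0L
        }
      }
    }
    n_edge <- min(len, trunc(0.2 * fs / r + 0.5))
    if (n_edge > 0) {
      lab[1:n_edge] <- -1L
      lab[(len - n_edge + 1L):len] <- -1L
    }
    lab
  })
}

# exhaustive NMS oracle: repeatedly pick the global best remaining
# candidate, delete everything within the window
oracle_nms <- function(samples, probs, fs, window_ms) {
  win_s <- window_ms / 1000 + 1e-9   # same closed-boundary guard as nms()
  keep_s <- integer(0); keep_p <- numeric(0)
  alive <- rep(TRUE, length(samples))
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-probs[cand], samples[cand])][1]
    keep_s <- c(keep_s, samples[best]); keep_p <- c(keep_p, probs[best])
    alive <- alive & abs(samples / fs - samples[best] / fs) > win_s
  }
  ord <- order(keep_s)
  list(sample = keep_s[ord], prob = keep_p[ord])
}

# brute-force nearest-assignment matching oracle: detections in time
# order, each taking the nearest still-free annotation within tolerance
oracle_match <- function(det, ann, fs, tol_s) {
  free <- rep(TRUE, length(ann))
  tp <- 0L
  for (d in det) {
    if (!any(free)) next
    cand <- which(free)
    dist <- abs(ann[cand] - d) / fs
    j <- cand[order(dist, ann[cand])][1]
    if (min(dist) < tol_s) {
      tp <- tp + 1L
      free[j] <- FALSE
    }
  }
  list(tp = tp, fp = length(det) - tp, fn = sum(free))
}
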