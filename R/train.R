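# Training: masked binary cross-entropy over the three heat maps,
# 60-s segmenting, augmentation policy, Adam, best-on-validation
# checkpoint selection.

BCE_CLAMP <- 1e-7

#' Masked binary cross-entropy over the three heat maps
#'
#' Per resolution, the mean binary cross-entropy over samples whose label
#' is not the ignore value (-1); the total is the unweighted mean of the
#' per-resolution losses, dropping any resolution with no valid samples.
#' Predictions are clamped to `[1e-7, 1 - 1e-7]`. Predictions at ignored
#' positions never influence the value.
#'
#' @param pred a `qrs_heatmaps` object (or a bare list of three maps).
#' @param target a [make_targets()] result with matching lengths.
#' @return scalar loss.
#' @export
masked_bce <- function(pred, target) {
  maps <- if (inherits(pred, "qrs_heatmaps")) pred$maps else pred
  masked_bce_grad(maps, target, want_grad = FALSE)$loss
}

masked_bce_grad <- function(maps, target, want_grad = TRUE) {
  labels <- target$labels
  per_map <- numeric(0)
  used <- integer(0)
  grads <- vector("list", 3L)
  for (i in 1:3) {
    p <- maps[[i]]
    y <- labels[[i]]
    abort_if(length(p) != length(y),
             sprintf("map %d: prediction length %d != target length %d",
                     i, length(p), length(y)))
    valid <- y != -1L
    nv <- sum(valid)
    grads[[i]] <- numeric(length(p))
    if (nv == 0L) next
    pc <- pmin(pmax(p[valid], BCE_CLAMP), 1 - BCE_CLAMP)
    yv <- y[valid]
    per_map <- c(per_map, -mean(yv * log(pc) + (1 - yv) * log(1 - pc)))
    used <- c(used, i)
    if (want_grad) grads[[i]][valid] <- (pc - yv) / (pc * (1 - pc)) / nv
  }
  abort_if(length(used) == 0L, "all three resolutions fully masked")
  if (want_grad) {
    for (i in used) grads[[i]] <- grads[[i]] / length(used)
  }
  list(loss = mean(per_map), dmaps = grads)
}

#' Slice a record into fixed-length training segments
#'
#' Non-overlapping consecutive windows of `seg_s` seconds; a final
#' partial window is dropped. Annotations are re-indexed to window-local
#' 0-based samples, preserving counts within kept windows.
#'
#' @param rec an [ecg_record()].
#' @param seg_s segment length in seconds (default 60).
#' @return list of [ecg_record()] segments.
#' @export
slice_segments <- function(rec, seg_s = 60) {
  n_seg_samples <- round(seg_s * rec$fs)
  n_windows <- nrow(rec$signal) %/% n_seg_samples
  lapply(seq_len(n_windows), function(w) {
    lo <- (w - 1L) * n_seg_samples          # 0-based window start
    sig <- rec$signal[(lo + 1L):(lo + n_seg_samples), , drop = FALSE]
    ann <- rec$annotations
    keep <- ann$sample >= lo & ann$sample < lo + n_seg_samples
    ann <- ann[keep, , drop = FALSE]
    ann$sample <- ann$sample - lo
    ecg_record(sig, fs = rec$fs, lead_names = rec$lead_names,
               annotations = ann,
               record_id = sprintf("%s_w%03d", rec$record_id, w),
               preprocessed = rec$preprocessed)
  })
}

# canonicalise a record unless already done
canonical <- function(rec) if (rec$preprocessed) rec else preprocess_record(rec)

# one (signal, targets) training example from a canonical segment
segment_example <- function(seg) {
  list(x = seg$signal,
       targets = make_targets(seg$annotations$sample, nrow(seg$signal),
                              fs = seg$fs))
}

# augmentation policy: optional BW/MA/EM noise at a uniform SNR, then
# per-channel flip and channel swap, each with probability 1/2
augment_segment <- function(x, fs, noise_p = 0.3, snr_range = c(4, 12)) {
  if (stats::runif(1) < noise_p) {
    n <- nrow(x)
    kind <- sample(c("bw", "ma", "em"), 1)
    noise <- switch(kind,
      bw = cbind(gen_baseline_wander(n, fs), gen_baseline_wander(n, fs)),
      ma = cbind(gen_muscle_artifact(n), gen_muscle_artifact(n)),
      em = cbind(gen_electrode_motion(n, fs), gen_electrode_motion(n, fs)))
    x <- mix_at_snr(x, noise, stats::runif(1, snr_range[1], snr_range[2]))
  }
  augment_channels(x, flip = stats::runif(2) < 0.5, swap = stats::runif(1) < 0.5)
}

# freshly simulated high-heart-rate segment, canonical form
simulated_example <- function(seg_s, fs = 250) {
  cfg <- sim_config(fs = fs, duration_s = seg_s,
                    bpm = stats::runif(1, 200, 280),
                    qrs_amp_mv = stats::runif(1, 3, 5),
                    qrs_dur_ms = stats::runif(1, 50, 100),
                    snr_db = stats::runif(1, 4, 12), seed = NULL)
  segment_example(canonical(simulate_segment(cfg)))
}

#' Train the detector
#'
#' Records are canonicalised, sliced into `seg_s`-second windows and
#' supervised with three-resolution ignore-label targets under masked
#' binary cross-entropy. Each epoch shuffles the segments; a fraction
#' `sim_frac` of batches is replaced by freshly simulated high-heart-rate
#' segments (200-280 BPM), and real segments receive the noise/flip/swap
#' augmentation policy. Optimization is Adam. After every epoch the mean
#' validation loss is computed; the returned model is the checkpoint with
#' the lowest validation loss (ties resolve to the earlier epoch).
#' Runs are reproducible given `seed`.
#'
#' @param model a `qrs_model` to train.
#' @param train_records,val_records lists of [ecg_record()]s.
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 5); 0 returns the initial
#'   weights unchanged.
#' @param batch_size segments per optimization step (default 32).
#' @param weight_decay L2 penalty added to gradients (default 1e-8).
#' @param seg_s training segment length in seconds (default 60).
#' @param seed integer seed or `NULL`.
#' @param sim_frac fraction of batches drawn from the high-heart-rate
#'   simulator (default 0.1).
#' @param noise_p per-segment probability of mixing one of baseline
#'   wander / muscle artifact / electrode motion noise (default 0.3).
#' @param verbose print per-epoch losses.
#' @return a `qrs_fit` object: `model` (best checkpoint), `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`), `best_epoch`.
#' @export
fit_qrs <- function(model, train_records, val_records, lr = 1e-3,
                    epochs = 5L, batch_size = 32L, weight_decay = 1e-8,
                    seg_s = 60, seed = NULL, sim_frac = 0.1, noise_p = 0.3,
                    verbose = FALSE) {
  abort_if(length(train_records) < 1 || length(val_records) < 1,
           "need at least one training and one validation record")
  with_seed(seed, {
    cfg <- model$cfg
    train_segs <- unlist(lapply(train_records,
                                function(r) slice_segments(canonical(r), seg_s)),
                         recursive = FALSE)
    val_segs <- unlist(lapply(val_records,
                              function(r) slice_segments(canonical(r), seg_s)),
                       recursive = FALSE)
    abort_if(length(train_segs) == 0L, "no complete training segments")
    train_ex <- lapply(train_segs, segment_example)
    val_ex <- lapply(val_segs, segment_example)

    val_loss_of <- function(params) {
      mean(vapply(val_ex, function(ex) {
        out <- nn_forward(params, cfg, ex$x, training = FALSE)
        masked_bce_grad(out$maps, ex$targets, want_grad = FALSE)$loss
      }, numeric(1)))
    }

    params <- model$params
    opt <- adam_init(params)
    history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                              val_loss = numeric())
    best_params <- params
    best_val <- Inf
    best_epoch <- 0L
    for (ep in seq_len(epochs)) {
      order <- sample(length(train_ex))
      batch_starts <- seq(1L, length(order), by = batch_size)
      ep_losses <- numeric(0)
      for (bs in batch_starts) {
        idx <- order[bs:min(bs + batch_size - 1L, length(order))]
        use_sim <- stats::runif(1) < sim_frac
        gsum <- NULL
        lsum <- 0
        for (i in idx) {
          ex <- if (use_sim) simulated_example(seg_s)
                else {
                  e <- train_ex[[i]]
                  list(x = augment_segment(e$x, 250, noise_p = noise_p),
                       targets = e$targets)
                }
          out <- nn_forward(params, cfg, ex$x, training = TRUE)
          lg <- masked_bce_grad(out$maps, ex$targets)
          abort_if(!is.finite(lg$loss),
                   sprintf("non-finite loss in epoch %d; aborting", ep))
          g <- nn_backward(params, cfg, out$cache, lg$dmaps)
          gsum <- if (is.null(gsum)) g
                  else mapply(function(a, b) a + b, gsum, g, SIMPLIFY = FALSE)
          lsum <- lsum + lg$loss
        }
        gmean <- lapply(gsum, function(g) g / length(idx))
        step <- adam_step(params, gmean, opt, lr = lr,
                          weight_decay = weight_decay)
        params <- step$params
        opt <- step$state
        ep_losses <- c(ep_losses, lsum / length(idx))
      }
      vl <- val_loss_of(params)
      history <- tibble::add_row(history, epoch = ep,
                                 train_loss = mean(ep_losses), val_loss = vl)
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_epoch <- ep
      }
      if (verbose) {
        message(sprintf("epoch %d: train %.4f  val %.4f%s", ep,
                        mean(ep_losses), vl,
                        if (best_epoch == ep) " *" else ""))
      }
    }
    best_model <- structure(list(cfg = cfg, params = best_params),
                            class = "qrs_model")
    structure(list(model = best_model, history = history,
                   best_epoch = best_epoch,
                   hyper = list(lr = lr, epochs = epochs,
                                batch_size = batch_size,
                                weight_decay = weight_decay, seg_s = seg_s,
                                sim_frac = sim_frac, noise_p = noise_p,
                                seed = seed)),
              class = "qrs_fit")
  })
}

#' @export
print.qrs_fit <- function(x, ...) {
  cat(sprintf("<qrs_fit> %d epoch(s), best epoch %d\n",
              nrow(x$history), x$best_epoch))
  if (nrow(x$history) > 0) print(x$history)
  invisible(x)
}
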