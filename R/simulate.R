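# Synthetic annotated ECG and the three standard ECG noise processes
# (baseline wander, muscle artifact, electrode motion), used both for
# data augmentation with high-heart-rate segments and as a fully
# self-contained source of test data.

#' Simulation configuration
#'
#' Parameter ranges follow the augmentation protocol: heart rate 200-280
#' BPM in high-heart-rate mode (40-180 BPM for general fixtures), QRS
#' amplitude 3-5 mV, QRS duration 50-100 ms, white noise at 4-12 dB SNR.
#'
#' @param fs sampling rate, Hz.
#' @param duration_s segment length, seconds.
#' @param bpm heart rate, beats per minute; `bpm * duration_s / 60 >= 1`.
#' @param qrs_amp_mv QRS peak amplitude, millivolts.
#' @param qrs_dur_ms total QRS duration, milliseconds.
#' @param snr_db white-noise signal-to-noise ratio in dB
#'   (`10*log10(P_clean / P_noise)`); `Inf` disables the noise.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs = 250, duration_s = 10, bpm = 240, qrs_amp_mv = 4,
                       qrs_dur_ms = 80, snr_db = 6, seed = NULL) {
  abort_if(fs <= 0 || duration_s <= 0, "fs and duration_s must be positive")
  abort_if(bpm <= 0, "bpm must be positive")
  abort_if(bpm * duration_s / 60 < 1, "segment too short to hold one beat")
  abort_if(qrs_amp_mv <= 0 || qrs_dur_ms <= 0, "QRS amplitude/duration must be positive")
  structure(list(fs = fs, duration_s = duration_s, bpm = bpm,
                 qrs_amp_mv = qrs_amp_mv, qrs_dur_ms = qrs_dur_ms,
                 snr_db = snr_db, seed = seed),
            class = "sim_config")
}

#' Default QRS waveform template
#'
#' Biphasic pulse with a sharp dominant R peak at its center and a smaller
#' trailing S dip, built from two Gaussians; compact support of the given
#' total duration, unit peak amplitude. The simulator accepts any function
#' with this signature, so other morphologies can be plugged in.
#'
#' @param t time offsets from the pulse center, seconds.
#' @param dur_s total pulse duration, seconds.
#' @return waveform values at `t`, peak normalized to 1.
#' @export
qrs_waveform <- function(t, dur_s) {
  sigma_r <- dur_s / 8
  sigma_s <- dur_s / 10
  w <- exp(-t^2 / (2 * sigma_r^2)) -
    0.4 * exp(-(t - dur_s / 4)^2 / (2 * sigma_s^2))
  w[abs(t) > dur_s / 2] <- 0
  w / max(w)
}

#' Simulate an annotated ECG segment
#'
#' Beats are placed at regular RR intervals of `60 / bpm` seconds, the
#' first at half an interval, so a segment holds exactly
#' `round(bpm * duration_s / 60)` beats. Each beat is rendered with the
#' waveform template at the configured amplitude and duration, white noise
#' is mixed at the configured SNR over the segment, and the second lead is
#' the first scaled by 0.8. Annotations mark the rendered pulse centers
#' (the R-peak sample). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param waveform pulse template function, default [qrs_waveform()].
#' @return an [ecg_record()] with all beats annotated as `"N"`.
#' @export
simulate_segment <- function(cfg, waveform = qrs_waveform) {
  abort_if(!inherits(cfg, "sim_config"), "cfg must come from sim_config()")
  with_seed(cfg$seed, {
    n <- round(cfg$fs * cfg$duration_s)
    rr <- 60 / cfg$bpm
    n_beats <- round(cfg$bpm * cfg$duration_s / 60)
    beat_t <- rr / 2 + rr * (seq_len(n_beats) - 1)
    beat_samples <- pmin(round(beat_t * cfg$fs), n - 1L)
    dur_s <- cfg$qrs_dur_ms / 1000
    half <- ceiling(dur_s / 2 * cfg$fs)
    lead1 <- numeric(n)
    # render each pulse on its local support, center locked to the annotation
    offs <- (-half):half
    template <- waveform(offs / cfg$fs, dur_s)
    template <- cfg$qrs_amp_mv * template / max(template)
    for (s in beat_samples) {
      idx <- s + offs + 1L
      ok <- idx >= 1L & idx <= n
      lead1[idx[ok]] <- lead1[idx[ok]] + template[ok]
    }
    clean <- cbind(lead1, 0.8 * lead1, deparse.level = 0)
    sig <- if (is.finite(cfg$snr_db)) {
      noise <- matrix(stats::rnorm(2L * n), n, 2)
      mix_at_snr(clean, noise, cfg$snr_db)
    } else clean
    ann <- tibble::tibble(sample = as.integer(beat_samples),
                          symbol = "N", aami = "N")
    ecg_record(sig, fs = cfg$fs, lead_names = c("sim1", "sim2"),
               annotations = ann,
               record_id = sprintf("sim%03.0f", cfg$seed %||% 0))
  })
}

#' Baseline-wander noise
#'
#' A single sinusoid whose frequency is drawn from an equal-probability
#' mixture of three Gaussians with means 0.05, 0.15, 0.25 Hz and standard
#' deviations one third of the mean (non-positive draws rejected), with a
#' uniform random phase.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param amp_z amplitude (z-units when mixed into normalized signals).
#' @param seed integer seed or `NULL`.
#' @return numeric vector of length `n`.
#' @export
gen_baseline_wander <- function(n, fs, amp_z = 1, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, {
    f <- draw_bw_frequency(1)
    phase <- stats::runif(1, 0, 2 * pi)
    amp_z * sin(2 * pi * f * (seq_len(n) - 1) / fs + phase)
  })
}

# frequency draws for baseline wander (exposed for distribution checks)
draw_bw_frequency <- function(n) {
  means <- c(0.05, 0.15, 0.25)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      m <- sample(means, 1)
      f <- stats::rnorm(1, m, m / 3)
      if (f > 0) break
    }
    out[i] <- f
  }
  out
}

#' Muscle-artifact noise
#'
#' White noise: i.i.d. standard Gaussian samples (the scale is set later
#' by SNR-controlled mixing).
#'
#' @param n number of samples.
#' @param seed integer seed or `NULL`.
#' @return numeric vector of length `n`.
#' @export
gen_muscle_artifact <- function(n, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, stats::rnorm(n))
}

#' Electrode-motion noise
#'
#' White noise band-passed to 5-15 Hz with the same zero-phase Butterworth
#' design used in preprocessing.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param seed integer seed or `NULL`.
#' @return numeric vector of length `n`.
#' @export
gen_electrode_motion <- function(n, fs, seed = NULL) {
  abort_if(n <= 0, "n must be positive")
  with_seed(seed, bandpass(stats::rnorm(n), fs, low = 5, high = 15))
}

#' Mix noise into a clean signal at an exact SNR
#'
#' Returns `clean + alpha * noise` with `alpha` chosen so that
#' `10*log10(P_clean / P_scaled_noise)` equals `snr_db` exactly, powers
#' measured over the whole segment (all leads).
#'
#' @param clean numeric vector or matrix with nonzero power.
#' @param noise numeric vector or matrix of the same shape, nonzero power.
#' @param snr_db requested signal-to-noise ratio in dB.
#' @return mixed signal, same shape as `clean`.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  abort_if(length(clean) != length(noise), "clean and noise must match in size")
  p_clean <- mean(clean^2)
  p_noise <- mean(noise^2)
  abort_if(p_clean == 0, "clean signal has zero power")
  abort_if(p_noise == 0, "noise has zero power")
  alpha <- sqrt(p_clean / (p_noise * 10^(snr_db / 10)))
  clean + alpha * noise
}

#' Channel flip/swap augmentation
#'
#' Per-channel sign inversion followed by an optional channel swap; both
#' operations are involutions, so applying the same arguments twice is the
#' identity.
#'
#' @param signal `n x 2` numeric matrix.
#' @param flip logical pair; channel `i` is negated where `flip[i]` is TRUE.
#' @param swap logical; exchange the two columns.
#' @return augmented `n x 2` matrix.
#' @export
augment_channels <- function(signal, flip = c(FALSE, FALSE), swap = FALSE) {
  x <- as_signal_matrix(signal)
  abort_if(ncol(x) != 2L, "augment_channels expects a two-channel signal")
  if (isTRUE(flip[[1]])) x[, 1] <- -x[, 1]
  if (isTRUE(flip[[2]])) x[, 2] <- -x[, 2]
  if (isTRUE(swap)) x <- x[, c(2L, 1L), drop = FALSE]
  x
}

#' Simulate a mixed-rate training corpus
#'
#' Draws per-record heart rates uniformly from `bpm_range`, with a
#' `high_hr_frac` fraction of records drawn from the high-heart-rate
#' augmentation range `high_hr_range` instead; QRS amplitude, duration and
#' white-noise SNR are drawn uniformly from the stated simulation ranges.
#'
#' @param n_records number of records to simulate.
#' @param duration_s record length in seconds (default 60).
#' @param bpm_range general heart-rate range (default 50-130 BPM).
#' @param high_hr_frac fraction of high-heart-rate records (default 0.1).
#' @param high_hr_range high-heart-rate range (default 200-280 BPM).
#' @param snr_range white-noise SNR range in dB (default 4-12); use
#'   `c(Inf, Inf)` for clean records.
#' @param fs sampling rate, Hz.
#' @param seed integer seed or `NULL`.
#' @return list of [ecg_record()]s.
#' @export
simulate_corpus <- function(n_records, duration_s = 60,
                            bpm_range = c(50, 130), high_hr_frac = 0.1,
                            high_hr_range = c(200, 280),
                            snr_range = c(4, 12), fs = 250, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n_records), function(i) {
      high <- stats::runif(1) < high_hr_frac
      bpm <- if (high) stats::runif(1, high_hr_range[1], high_hr_range[2])
             else stats::runif(1, bpm_range[1], bpm_range[2])
      snr <- if (all(is.infinite(snr_range))) Inf
             else stats::runif(1, snr_range[1], snr_range[2])
      cfg <- sim_config(fs = fs, duration_s = duration_s, bpm = bpm,
                        qrs_amp_mv = stats::runif(1, 3, 5),
                        qrs_dur_ms = stats::runif(1, 50, 100),
                        snr_db = snr, seed = NULL)
      rec <- simulate_segment(cfg)
      rec$record_id <- sprintf("sim%04d", i)
      rec
    })
  })
}

#' Write a miniature synthetic WFDB dataset
#'
#' Generates train/validation/test splits of annotated synthetic records
#' and writes them as WFDB files — the fixture generator behind the
#' `qrspeak fixtures` CLI subcommand. Byte-identical for a given seed.
#'
#' @param dir output directory; `train/`, `val/`, `test/` subdirectories
#'   are created.
#' @param seed integer seed.
#' @param n_train,n_val,n_test records per split.
#' @param duration_s record length in seconds.
#' @return invisibly, a list of written header paths by split.
#' @export
write_fixture_dataset <- function(dir, seed = 1L, n_train = 4L, n_val = 2L,
                                  n_test = 2L, duration_s = 30) {
  splits <- list(train = n_train, val = n_val, test = n_test)
  out <- list()
  k <- 0L
  for (s in names(splits)) {
    sub <- file.path(dir, s)
    recs <- simulate_corpus(splits[[s]], duration_s = duration_s,
                            seed = seed + k)
    k <- k + 1L
    out[[s]] <- vapply(seq_along(recs), function(i) {
      recs[[i]]$record_id <- sprintf("%s%03d", s, i)
      write_record(recs[[i]], sub)
    }, character(1))
  }
  invisible(out)
}
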