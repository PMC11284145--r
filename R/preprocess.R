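# Canonical preprocessing: 250 Hz, 0.5-35 Hz zero-phase Butterworth
# band-pass, per-lead z-score, two channels.

#' Resample a record to a target rate
#'
#' Polyphase resampling (`signal::resample`) by the reduced rational
#' factor `target_fs / fs`. Annotation sample indices are rescaled by the
#' same factor and rounded to the nearest sample (ties half away from
#' zero); beat count and ordering are preserved.
#'
#' @param rec an [ecg_record()].
#' @param target_fs target sampling rate in Hz (default 250).
#' @return the resampled [ecg_record()].
#' @export
resample_record <- function(rec, target_fs = 250) {
  abort_if(!inherits(rec, "ecg_record"), "rec must be an ecg_record")
  if (isTRUE(all.equal(rec$fs, target_fs))) return(rec)
  frac <- rational_ratio(target_fs, rec$fs)
  n_out <- ceiling(nrow(rec$signal) * frac$p / frac$q)
  out <- matrix(0, n_out, ncol(rec$signal))
  for (i in seq_len(ncol(rec$signal))) {
    y <- signal::resample(rec$signal[, i], frac$p, frac$q)
    out[, i] <- y[seq_len(n_out)]
  }
  ann <- rec$annotations
  if (nrow(ann) > 0) {
    ann$sample <- as.integer(round_half_up(ann$sample * target_fs / rec$fs))
    ann$sample <- pmin(pmax(ann$sample, 0L), n_out - 1L)
    abort_if(is.unsorted(ann$sample, strictly = TRUE),
             "annotations collided during resampling (rate too low)")
  }
  ecg_record(out, fs = target_fs, lead_names = rec$lead_names,
             annotations = ann, record_id = rec$record_id,
             preprocessed = rec$preprocessed)
}

# reduced integer ratio p/q ~= a/b for (possibly non-integer) rates
rational_ratio <- function(a, b) {
  scale <- 1000
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd_int(p, q)
  list(p = p / g, q = q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward-backward (`signal::filtfilt`) per
#' lead, so filtering adds no group delay and annotated QRS positions stay
#' aligned with the waveform.
#'
#' @param signal numeric matrix (samples x leads) or vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 0.5 and 35).
#' @param order filter order (default 3).
#' @return filtered matrix with the input shape.
#' @export
bandpass <- function(signal, fs, low = 0.5, high = 35, order = 3L) {
  x <- as_signal_matrix(signal)
  abort_if(!(low > 0 && low < high), "need 0 < low < high")
  abort_if(high >= fs / 2, "high cutoff must be below the Nyquist rate")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # odd-reflection edge padding keeps the forward-backward pass free of
  # start-up transients (the 0.5 Hz edge settles slowly)
  n <- nrow(x)
  pad <- min(n - 1L, ceiling(3 * fs / low))
  out <- x
  for (i in seq_len(ncol(x))) {
    xi <- x[, i]
    pre <- 2 * xi[1] - xi[(pad + 1L):2L]
    post <- 2 * xi[n] - xi[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(pre, xi, post))
    out[, i] <- y[(pad + 1L):(pad + n)]
  }
  if (is.null(dim(signal))) out[, 1] else out
}

#' Z-score each lead
#'
#' Centers and scales every column to mean 0 and (sample) standard
#' deviation 1. A zero-variance lead maps to all zeros rather than
#' dividing by zero, so flat-line segments survive batch pipelines.
#'
#' @param signal numeric matrix (samples x leads) or vector.
#' @return matrix of the input shape (vector in, vector out).
#' @export
zscore_leads <- function(signal) {
  x <- as_signal_matrix(signal)
  abort_if(nrow(x) < 2, "need at least 2 samples per lead")
  out <- x
  for (i in seq_len(ncol(x))) {
    s <- stats::sd(x[, i])
    out[, i] <- if (s == 0 || !is.finite(s)) 0 else (x[, i] - mean(x[, i])) / s
  }
  if (is.null(dim(signal))) out[, 1] else out
}

#' Ensure a two-channel signal
#'
#' The detector has two input channels; single-lead signals are duplicated
#' into the second channel, two-lead signals pass through unchanged.
#'
#' @param signal numeric matrix with 1 or 2 columns (or a vector).
#' @return an `n x 2` matrix.
#' @export
ensure_dual_channel <- function(signal) {
  x <- as_signal_matrix(signal)
  abort_if(nrow(x) == 0, "empty signal")
  abort_if(ncol(x) > 2, "more than two leads; truncate on input")
  if (ncol(x) == 1L) x <- cbind(x, x, deparse.level = 0)
  x
}

#' Full canonical preprocessing
#'
#' Resample to 250 Hz, band-pass 0.5-35 Hz (zero phase), z-score each
#' lead, and duplicate single leads to two channels. This is the exact
#' representation the model is trained on.
#'
#' @param rec an [ecg_record()].
#' @param target_fs canonical rate, default 250 Hz.
#' @param low,high band-pass edges in Hz.
#' @return a canonical [ecg_record()] with `preprocessed = TRUE`.
#' @export
preprocess_record <- function(rec, target_fs = 250, low = 0.5, high = 35) {
  rec <- resample_record(rec, target_fs)
  sig <- bandpass(rec$signal, rec$fs, low, high)
  sig <- zscore_leads(sig)
  sig <- ensure_dual_channel(sig)
  lead_names <- if (ncol(rec$signal) == 1L) rep(rec$lead_names, 2) else rec$lead_names
  ecg_record(sig, fs = rec$fs, lead_names = lead_names,
             annotations = rec$annotations, record_id = rec$record_id,
             preprocessed = TRUE)
}
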