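# Detection: thresholded local maxima on a heat map, then greedy
# non-maximum suppression within a temporal window.

new_detections <- function(sample, prob, fs, record_id = "record") {
  out <- tibble::tibble(sample = as.integer(sample), prob = as.numeric(prob))
  attr(out, "fs") <- fs
  attr(out, "record_id") <- record_id
  class(out) <- c("qrs_detections", class(out))
  out
}

#' Find QRS candidates on a heat map
#'
#' A sample is a candidate iff its value exceeds `thr` and it is a local
#' maximum. Plateaus (runs of equal values higher than both neighbouring
#' runs, with the map edges counting as minus infinity) emit a single
#' candidate at the run centre, left-of-centre for even run lengths.
#'
#' @param map numeric probability vector in `[0, 1]`.
#' @param fs sampling rate of the map, Hz.
#' @param thr detection threshold (default 0.5).
#' @return a `qrs_detections` tibble with 0-based `sample` and `prob`.
#' @export
find_candidates <- function(map, fs, thr = 0.5) {
  r <- rle(map)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  left <- c(-Inf, r$values[-nruns])
  right <- c(r$values[-1L], -Inf)
  is_max <- r$values > thr & r$values > left & r$values > right
  centers <- starts + (r$lengths - 1L) %/% 2L
  new_detections(centers[is_max] - 1L, r$values[is_max], fs = fs)
}

#' Greedy non-maximum suppression
#'
#' Candidates are sorted by descending probability (ties to the earlier
#' sample); the top candidate is accepted and every remaining candidate
#' within `window_ms` of it (closed interval, compared in seconds)
#' discarded, until none remain. Accepted detections are returned in
#' ascending sample order, so consecutive detections are always more than
#' the window apart.
#'
#' @param cands a `qrs_detections` tibble of candidates.
#' @param fs sampling rate the samples refer to, Hz.
#' @param window_ms suppression window in milliseconds (default 200).
#' @return a `qrs_detections` tibble.
#' @export
nms <- function(cands, fs, window_ms = 200) {
  if (nrow(cands) == 0L) {
    return(new_detections(integer(), numeric(), fs = fs,
                          record_id = attr(cands, "record_id") %||% "record"))
  }
  ord <- order(-cands$prob, cands$sample)
  t_s <- cands$sample[ord] / fs
  p <- cands$prob[ord]
  # closed suppression interval; the 1 ns guard keeps exact-boundary
  # offsets (integer samples mapping onto the window edge) suppressed
  # regardless of floating-point rounding
  win_s <- window_ms / 1000 + 1e-9
  alive <- rep(TRUE, length(ord))
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (!alive[[i]]) next
    keep[[i]] <- TRUE
    alive <- alive & abs(t_s - t_s[[i]]) > win_s
  }
  sel <- which(keep)
  sel <- sel[order(cands$sample[ord][sel])]
  new_detections(cands$sample[ord][sel], p[sel], fs = fs,
                 record_id = attr(cands, "record_id") %||% "record")
}

#' Detect QRS complexes in a record
#'
#' Canonicalises the record (250 Hz, band-pass, z-score, two channels)
#' unless already done, runs the model, extracts candidates from the
#' requested heat map (full resolution by default), applies non-maximum
#' suppression, and maps the detections back to the record's native
#' sample coordinates.
#'
#' @param model a trained `qrs_model`.
#' @param rec an [ecg_record()].
#' @param thr detection threshold (default 0.5).
#' @param window_ms suppression window in milliseconds (default 200).
#' @param map which heat map drives detection: 1 full, 2 half, 3 quarter
#'   resolution (default 1).
#' @return a `qrs_detections` tibble in native-rate sample coordinates.
#' @export
detect_record <- function(model, rec, thr = 0.5, window_ms = 200, map = 1L) {
  abort_if(!inherits(rec, "ecg_record"), "rec must be an ecg_record")
  native_fs <- rec$fs
  canon <- canonical(rec)
  hm <- forward(model, canon$signal)
  m <- hm$maps[[map]]
  map_fs <- hm$fs_per_map[[map]]
  cands <- find_candidates(m, fs = map_fs, thr = thr)
  det <- nms(cands, fs = map_fs, window_ms = window_ms)
  native_samples <- as.integer(round_half_up(det$sample / map_fs * native_fs))
  new_detections(native_samples, det$prob, fs = native_fs,
                 record_id = rec$record_id)
}
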