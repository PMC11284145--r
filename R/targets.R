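# Training targets: three-resolution label vectors over {1, 0, -1}.
#
# Heat-map supervision with an ignore label: samples closer than 75 ms to
# the nearest annotated beat are positive, samples farther than 150 ms
# (and lying strictly between the first and last beat) are negative, the
# 75-150 ms border zone and everything outside the annotated span is
# ignored (-1), as are the first and last 200 ms of every map.

#' Build three-resolution training targets from beat annotations
#'
#' For map resolution `r` in {1, 2, 4} the grid point `i` sits at time
#' `i * r / fs` (left-aligned grid, 0-based, matching stride-2
#' downsampling). With `d(i)` the distance to the nearest annotation:
#' label 1 if `d < 0.075` s; label 0 if `d > 0.150` s **and** the point
#' lies strictly between the first and last annotation; otherwise -1.
#' Boundary distances of exactly 75 or 150 ms fall in the ignore band.
#' Finally the first and last `0.2` s of each map are forced to -1 so
#' incomplete edge beats never drive the loss. With no annotations every
#' label is -1.
#'
#' @param annotations integer vector of 0-based full-resolution sample
#'   indices of the annotated beats, sorted strictly increasing, in
#'   `[0, l)`.
#' @param l full-resolution length in samples.
#' @param fs full-resolution sampling rate, Hz (default 250).
#' @param pos_s,neg_s positive / negative distance thresholds in seconds.
#' @param edge_s edge mask width in seconds.
#' @return a `qrs_targets` object: `labels` (list of three integer
#'   vectors of lengths `l`, `ceiling(l/2)`, `ceiling(l/4)`) and
#'   `fs_per_map`.
#' @export
make_targets <- function(annotations, l, fs = 250, pos_s = 0.075,
                         neg_s = 0.150, edge_s = 0.2) {
  abort_if(l < 1, "l must be positive")
  ann <- as.numeric(annotations)
  abort_if(length(ann) > 0 && is.unsorted(ann, strictly = TRUE),
           "annotations must be sorted strictly increasing")
  abort_if(length(ann) > 0 && (min(ann) < 0 || max(ann) >= l),
           "annotations must lie in [0, l)")
  t_ann <- ann / fs
  labels <- lapply(c(1L, 2L, 4L), function(r) {
    len <- ceiling(l / r)
    lab <- rep(-1L, len)
    if (length(t_ann) > 0) {
      t_i <- (seq_len(len) - 1) * r / fs
      d <- nearest_distance(t_i, t_ann)
      lab[d < pos_s] <- 1L
      inside <- t_i > t_ann[[1]] & t_i < t_ann[[length(t_ann)]]
      lab[inside & d > neg_s] <- 0L
    }
    n_edge <- min(len, round_half_up(edge_s * fs / r))
    if (n_edge > 0) {
      lab[seq_len(n_edge)] <- -1L
      lab[seq.int(len - n_edge + 1L, len)] <- -1L
    }
    lab
  })
  structure(list(labels = labels, fs_per_map = fs / c(1, 2, 4), l = l),
            class = "qrs_targets")
}

# distance from each sorted query time to the nearest of sorted ref times
nearest_distance <- function(t, ref) {
  idx <- findInterval(t, ref)
  lo <- ifelse(idx >= 1, ref[pmax(idx, 1L)], Inf)
  hi <- ifelse(idx < length(ref), ref[pmin(idx + 1L, length(ref))], Inf)
  pmin(abs(t - lo), abs(hi - t))
}

#' @export
print.qrs_targets <- function(x, ...) {
  cat(sprintf("<qrs_targets> l=%d at %g Hz\n", x$l, x$fs_per_map[[1]]))
  for (i in 1:3) {
    tab <- table(factor(x$labels[[i]], levels = c(-1, 0, 1)))
    cat(sprintf("  map %d (len %d): +1=%d  0=%d  -1=%d\n", i,
                length(x$labels[[i]]), tab[["1"]], tab[["0"]], tab[["-1"]]))
  }
  invisible(x)
}
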