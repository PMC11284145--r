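# EC57-style evaluation: tolerance-window beat matching, Sen/Pre/Err,
# per-type false-negative rates, timing-margin statistics.

#' Match detections to annotated beats
#'
#' One-to-one greedy matching: detections are processed in ascending
#' time; each matches the nearest not-yet-matched annotation when the
#' absolute offset is strictly below `tol_s` seconds (equidistant ties
#' resolve to the earlier annotation), otherwise it is a false positive.
#' Annotations left unmatched are false negatives.
#'
#' @param detections integer vector of detection samples (0-based),
#'   sorted ascending.
#' @param annotations integer vector of annotated beat samples (0-based),
#'   sorted ascending.
#' @param fs sampling rate both index sets refer to, Hz.
#' @param tol_s matching tolerance in seconds (default 0.15; use 0.075
#'   for the stricter convention).
#' @return list with `pairs` (tibble `det`, `ann`, `dt_s`), `fp`
#'   (unmatched detection samples) and `fn` (unmatched annotation
#'   samples).
#' @export
match_beats <- function(detections, annotations, fs, tol_s = 0.15) {
  abort_if(is.unsorted(detections), "detections must be sorted")
  abort_if(is.unsorted(annotations), "annotations must be sorted")
  nd <- length(detections); na <- length(annotations)
  matched <- rep(FALSE, na)
  pair_det <- integer(0); pair_ann <- integer(0)
  t_det <- detections / fs
  t_ann <- annotations / fs
  for (i in seq_len(nd)) {
    td <- t_det[[i]]
    j0 <- findInterval(td, t_ann)
    best <- 0L; best_d <- Inf
    j <- j0                                 # scan left
    while (j >= 1L && td - t_ann[[j]] < tol_s) {
      if (!matched[[j]]) {
        d <- td - t_ann[[j]]
        if (d < best_d || (d == best_d && (best == 0L || j < best))) {
          best <- j; best_d <- d
        }
      }
      j <- j - 1L
    }
    j <- j0 + 1L                            # scan right
    while (j <= na && t_ann[[j]] - td < tol_s) {
      if (!matched[[j]]) {
        d <- t_ann[[j]] - td
        if (d < best_d) { best <- j; best_d <- d }
      }
      j <- j + 1L
    }
    if (best > 0L) {
      matched[[best]] <- TRUE
      pair_det <- c(pair_det, detections[[i]])
      pair_ann <- c(pair_ann, annotations[[best]])
    }
  }
  pairs <- tibble::tibble(det = pair_det, ann = pair_ann,
                          dt_s = (pair_det - pair_ann) / fs)
  list(pairs = pairs,
       fp = setdiff(detections, pair_det),
       fn = annotations[!matched])
}

#' Sensitivity, precision and error rate from match counts
#'
#' `Sen = 100 TP / (TP + FN)`, `Pre = 100 TP / (TP + FP)`,
#' `Err = 100 (FP + FN) / (TP + FN + FP)`. Values are returned at full
#' precision; degenerate denominators give `NA` rather than an error, and
#' `Err` may exceed 100 when false positives dominate.
#'
#' @param tp,fp,fn non-negative counts.
#' @return tibble with columns `tp`, `fp`, `fn`, `sen`, `pre`, `err`.
#' @export
qrs_metrics <- function(tp, fp, fn) {
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  pre <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  err <- if (tp + fn + fp > 0) 100 * (fp + fn) / (tp + fn + fp) else NA_real_
  tibble::tibble(tp = tp, fp = fp, fn = fn, sen = sen, pre = pre, err = err)
}

#' Per-AAMI-type false-negative rates
#'
#' For each AAMI class present among the annotations,
#' `Fnr = 100 FN_type / (TP_type + FN_type)`; absent classes are omitted.
#'
#' @param fn_samples samples of missed (false-negative) annotations.
#' @param annotations annotation tibble with `sample` and `aami` columns.
#' @return tibble with columns `aami`, `n`, `fn`, `fnr`.
#' @export
fnr_by_type <- function(fn_samples, annotations) {
  if (nrow(annotations) == 0L) {
    return(tibble::tibble(aami = character(), n = integer(),
                          fn = integer(), fnr = numeric()))
  }
  missed <- annotations$sample %in% fn_samples
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(aami = annotations$aami, missed = missed),
                    .data$aami),
    n = dplyr::n(), fn = sum(.data$missed), .groups = "drop")
  agg$fnr <- 100 * agg$fn / agg$n
  agg
}

#' Timing-margin statistics over true positives
#'
#' Mean and sample standard deviation (n-1) of the absolute offsets
#' between matched detections and their annotations, in milliseconds. A
#' single pair reports sd 0; no pairs reports `NA`.
#'
#' @param pairs the `pairs` tibble from [match_beats()].
#' @return list with `mean_ms` and `sd_ms`.
#' @export
margin_stats <- function(pairs) {
  if (nrow(pairs) == 0L) return(list(mean_ms = NA_real_, sd_ms = NA_real_))
  m <- abs(pairs$dt_s) * 1000
  list(mean_ms = mean(m), sd_ms = if (length(m) > 1L) stats::sd(m) else 0)
}

#' Score detections against a record's annotations
#'
#' Runs tolerance-window matching and assembles the full evaluation
#' report: TP/FP/FN counts, Sen/Pre/Err, per-AAMI-type false-negative
#' rates and timing margins.
#'
#' @param det a `qrs_detections` tibble (native-rate samples).
#' @param rec the annotated [ecg_record()] the detections refer to, or a
#'   bare annotation tibble with `sample` and `aami` columns.
#' @param fs sampling rate; taken from `rec`/`det` when omitted.
#' @param tol_s matching tolerance in seconds (default 0.15).
#' @return a `qrs_eval` object.
#' @export
evaluate_detections <- function(det, rec, fs = NULL, tol_s = 0.15) {
  if (inherits(rec, "ecg_record")) {
    ann <- rec$annotations
    fs <- fs %||% rec$fs
    record_id <- rec$record_id
  } else {
    ann <- tibble::as_tibble(rec)
    if (!"aami" %in% names(ann)) ann$aami <- "N"
    fs <- fs %||% attr(det, "fs")
    record_id <- attr(det, "record_id") %||% "record"
  }
  abort_if(is.null(fs) || !is.finite(fs), "sampling rate unavailable")
  m <- match_beats(det$sample, ann$sample, fs = fs, tol_s = tol_s)
  counts <- qrs_metrics(tp = nrow(m$pairs), fp = length(m$fp),
                        fn = length(m$fn))
  structure(list(record_id = record_id, counts = counts,
                 fnr = fnr_by_type(m$fn, ann), margin = margin_stats(m$pairs),
                 pairs = m$pairs, fp = m$fp, fn = m$fn,
                 tolerance_s = tol_s, n_beats = nrow(ann),
                 n_detections = nrow(det)),
            class = "qrs_eval")
}

#' Pool evaluation reports over records
#'
#' Sums TP/FP/FN over per-record reports and recomputes the aggregate
#' metrics, type-wise false-negative rates and margins.
#'
#' @param evals list of `qrs_eval` objects.
#' @return a `qrs_eval` object for the pooled counts.
#' @export
aggregate_evals <- function(evals) {
  tp <- sum(vapply(evals, function(e) e$counts$tp, numeric(1)))
  fp <- sum(vapply(evals, function(e) e$counts$fp, numeric(1)))
  fn <- sum(vapply(evals, function(e) e$counts$fn, numeric(1)))
  fnr_all <- dplyr::bind_rows(lapply(evals, function(e) e$fnr))
  fnr <- dplyr::summarise(dplyr::group_by(fnr_all, .data$aami),
                          n = sum(.data$n), fn = sum(.data$fn),
                          .groups = "drop")
  if (nrow(fnr) > 0) fnr$fnr <- 100 * fnr$fn / fnr$n
  margins <- unlist(lapply(evals, function(e) abs(e$pairs$dt_s) * 1000))
  structure(list(record_id = "(pooled)", counts = qrs_metrics(tp, fp, fn),
                 fnr = fnr,
                 margin = list(mean_ms = if (length(margins)) mean(margins) else NA_real_,
                               sd_ms = if (length(margins) > 1) stats::sd(margins) else 0),
                 pairs = dplyr::bind_rows(lapply(evals, function(e) e$pairs)),
                 fp = NULL, fn = NULL,
                 tolerance_s = evals[[1]]$tolerance_s,
                 n_beats = sum(vapply(evals, function(e) e$n_beats, numeric(1))),
                 n_detections = sum(vapply(evals, function(e) e$n_detections, numeric(1)))),
            class = "qrs_eval")
}

#' @export
print.qrs_eval <- function(x, ...) {
  c <- x$counts
  cat(sprintf("<qrs_eval '%s'> tol %.3f s: %d beats, %d detections\n",
              x$record_id, x$tolerance_s, x$n_beats, x$n_detections))
  cat(sprintf("  TP %d  FP %d  FN %d | Sen %.2f  Pre %.2f  Err %.2f\n",
              c$tp, c$fp, c$fn, c$sen, c$pre, c$err))
  if (!is.na(x$margin$mean_ms)) {
    cat(sprintf("  margin %.2f +- %.2f ms\n", x$margin$mean_ms, x$margin$sd_ms))
  }
  if (nrow(x$fnr) > 0) {
    cat("  Fnr by type: ",
        paste(sprintf("%s %.2f%%", x$fnr$aami, x$fnr$fnr), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}
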