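#' ECG record container
#'
#' Bundles a multi-lead ECG signal with its sampling rate and beat
#' annotations. Annotation `sample` indices are 0-based (the WFDB
#' convention) so that `time = sample / fs`; when indexing the signal
#' matrix from R use `sample + 1`.
#'
#' @param signal numeric matrix, samples in rows, leads in columns
#'   (a plain vector is taken as one lead), in millivolts.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector of lead labels, recycled/defaulted
#'   to `"lead1"`, `"lead2"`, ...
#' @param annotations a data frame with columns `sample` (0-based integer
#'   index), `symbol` (WFDB beat symbol) and optionally `aami` (AAMI class,
#'   derived from `symbol` when absent), or `NULL` for none.
#' @param record_id record identifier used in file names and reports.
#' @param preprocessed logical flag marking the canonical representation
#'   (250 Hz, band-passed, z-scored, two channels).
#'
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = NULL, annotations = NULL,
                       record_id = "record", preprocessed = FALSE) {
  signal <- as_signal_matrix(signal)
  abort_if(nrow(signal) == 0L, "signal has zero length")
  abort_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0, "fs must be a positive scalar")
  n_leads <- ncol(signal)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(n_leads))
  abort_if(length(lead_names) != n_leads, "lead_names length must match lead count")
  annotations <- normalize_annotations(annotations, nrow(signal))
  structure(
    list(signal = signal, fs = as.numeric(fs), lead_names = as.character(lead_names),
         annotations = annotations, record_id = as.character(record_id),
         preprocessed = isTRUE(preprocessed)),
    class = "ecg_record"
  )
}

normalize_annotations <- function(annotations, n_samples) {
  if (is.null(annotations) || NROW(annotations) == 0L) {
    return(tibble::tibble(sample = integer(), symbol = character(), aami = character()))
  }
  ann <- tibble::as_tibble(annotations)
  abort_if(!"sample" %in% names(ann), "annotations need a 'sample' column")
  if (!"symbol" %in% names(ann)) ann$symbol <- "N"
  if (!"aami" %in% names(ann)) ann$aami <- map_symbol_to_aami(ann$symbol)
  ann <- ann[, c("sample", "symbol", "aami")]
  ann$sample <- as.integer(ann$sample)
  abort_if(any(ann$sample < 0L) || any(ann$sample >= n_samples),
           "annotation samples must lie in [0, n_samples)")
  abort_if(is.unsorted(ann$sample, strictly = TRUE),
           "annotation samples must be strictly increasing")
  ann
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples x %d lead(s) @ %g Hz (%.1f s)%s\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs,
              if (x$preprocessed) ", canonical" else ""))
  cat(sprintf("  leads: %s\n", paste(x$lead_names, collapse = ", ")))
  cat(sprintf("  beats: %d annotated", nrow(x$annotations)))
  if (nrow(x$annotations) > 0) {
    tab <- table(x$annotations$aami)
    cat(" (", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Duration of a record in seconds
#' @param rec an [ecg_record()].
#' @return numeric scalar, seconds.
#' @export
record_duration <- function(rec) nrow(rec$signal) / rec$fs
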