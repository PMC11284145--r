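# Named presets for users working with the public arrhythmia datasets.

#' MIT-BIH arrhythmia second-division train/validation split
#'
#' The record lists of the dataset split used to train and validate the
#' reference detector (second division of the arrhythmia database).
#' Using it requires the PhysioNet files on local disk; nothing is
#' downloaded by this package.
#'
#' @return list with `train` and `val` character vectors of record names.
#' @export
ar_ds2_split <- function() {
  list(
    train = c("100", "103", "105", "111", "113", "117", "121", "123",
              "200", "202", "210", "212", "213", "214", "219"),
    val = c("221", "222", "228", "231", "232", "233", "234")
  )
}

#' Load the AR_DS2 split from a directory of WFDB records
#'
#' Convenience wrapper around [read_record()] for users who have the
#' arrhythmia database locally: reads the [ar_ds2_split()] records from
#' `dir` and returns them ready for [fit_qrs()].
#'
#' @param dir directory containing `<record>.hea/.dat/.atr` files.
#' @return list with `train` and `val` lists of [ecg_record()]s.
#' @export
load_ar_ds2 <- function(dir) {
  split <- ar_ds2_split()
  lapply(split, function(ids) {
    lapply(ids, function(id) read_record(file.path(dir, id)))
  })
}
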