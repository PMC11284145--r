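# broom-style tidiers for evaluation reports and fitted models

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per AAMI beat type with its false-negative rate; the overall
#' counts live in [glance.qrs_eval()].
#'
#' @param x a `qrs_eval` object.
#' @param ... unused.
#' @return a tibble with `aami`, `n`, `fn`, `fnr`.
#' @export
tidy.qrs_eval <- function(x, ...) x$fnr

#' One-row summary of an evaluation report
#'
#' @param x a `qrs_eval` object.
#' @param ... unused.
#' @return a one-row tibble: counts, Sen/Pre/Err (percent), margin mean
#'   and sd (ms), tolerance (s) and beat/detection totals.
#' @export
glance.qrs_eval <- function(x, ...) {
  tibble::tibble(record_id = x$record_id, tp = x$counts$tp, fp = x$counts$fp,
                 fn = x$counts$fn, sen = x$counts$sen, pre = x$counts$pre,
                 err = x$counts$err, margin_mean_ms = x$margin$mean_ms,
                 margin_sd_ms = x$margin$sd_ms, tolerance_s = x$tolerance_s,
                 n_beats = x$n_beats, n_detections = x$n_detections)
}

#' Per-epoch training history
#'
#' @param x a `qrs_fit` object.
#' @param ... unused.
#' @return tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.qrs_fit <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x a `qrs_fit` object.
#' @param ... unused.
#' @return a one-row tibble with the best epoch, its validation loss and
#'   the main hyperparameters.
#' @export
glance.qrs_fit <- function(x, ...) {
  best_val <- if (nrow(x$history) > 0) {
    x$history$val_loss[match(x$best_epoch, x$history$epoch)]
  } else NA_real_
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = best_val, lr = x$hyper$lr,
                 batch_size = x$hyper$batch_size,
                 weight_decay = x$hyper$weight_decay,
                 n_parameters = count_parameters(x$model))
}
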