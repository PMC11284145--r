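# ggplot2 graphics for records, heat maps, detections and training runs

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ECG record
#'
#' Leads are faceted vertically; annotated beats are marked with vertical
#' lines.
#'
#' @param object an [ecg_record()].
#' @param from_s,to_s optional time window in seconds.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ecg_record <- function(object, from_s = 0,
                                to_s = record_duration(object), ...) {
  n <- nrow(object$signal)
  df <- tidyr::pivot_longer(
    dplyr::mutate(
      tibble::as_tibble(object$signal, .name_repair = ~object$lead_names),
      time_s = (seq_len(n) - 1) / object$fs),
    -"time_s", names_to = "lead", values_to = "mv")
  df <- dplyr::filter(df, .data$time_s >= from_s, .data$time_s <= to_s)
  ann_t <- object$annotations$sample / object$fs
  ann_t <- ann_t[ann_t >= from_s & ann_t <= to_s]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead)) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = object$record_id)
  if (length(ann_t) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ann_t, colour = "red",
                                 alpha = 0.3, linetype = 2)
  }
  p
}

#' Plot the three heat maps
#'
#' @param object a `qrs_heatmaps` object from [forward()].
#' @param ... unused.
#' @return a ggplot object with one facet per resolution.
#' @export
autoplot.qrs_heatmaps <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(
      map = sprintf("map %d (%g Hz)", i, object$fs_per_map[[i]]),
      time_s = (seq_along(object$maps[[i]]) - 1) / object$fs_per_map[[i]],
      prob = object$maps[[i]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$prob)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$map)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "QRS probability")
}

#' Plot training history
#'
#' @param object a `qrs_fit` object.
#' @param ... unused.
#' @return a ggplot object of train/validation loss per epoch.
#' @export
autoplot.qrs_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "masked BCE")
}

#' Overlay detections on a record
#'
#' First lead with annotated beats (red dashed) and detections (blue).
#'
#' @param rec an [ecg_record()].
#' @param det a `qrs_detections` tibble for that record.
#' @param from_s,to_s optional time window in seconds.
#' @return a ggplot object.
#' @export
plot_detections <- function(rec, det, from_s = 0, to_s = record_duration(rec)) {
  n <- nrow(rec$signal)
  df <- tibble::tibble(time_s = (seq_len(n) - 1) / rec$fs,
                       mv = rec$signal[, 1])
  df <- dplyr::filter(df, .data$time_s >= from_s, .data$time_s <= to_s)
  ann_t <- rec$annotations$sample / rec$fs
  det_t <- det$sample / rec$fs
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = ann_t[ann_t >= from_s & ann_t <= to_s],
                        colour = "red", linetype = 2, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = det_t[det_t >= from_s & det_t <= to_s],
                        colour = "blue", alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "amplitude", title = rec$record_id,
                  subtitle = "red dashed: annotated beats; blue: detections")
}
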