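#' Plot a multichannel recording
#'
#' Stacked per-channel signal traces.
#'
#' @param recording An `emg_recording`.
#' @param channels Channels to show; default all.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, channels = NULL) {
  if (is.null(channels)) {
    channels <- grep("^ch[0-9]+$", names(recording), value = TRUE)
  }
  long <- tidyr::pivot_longer(as_tibble(recording), dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "sEMG (signal units)")
}

#' @describeIn train_bpnn Training loss curve.
#' @export
autoplot.bpnn <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loss_curve),
               loss = object$loss_curve)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "summed cross-entropy loss")
}

#' @rdname relieff_weights
#' @param object A `relieff_weights` object.
#' @param ... Unused.
#' @export
autoplot.relieff_weights <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(.data$stat, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), nrow = 2) +
    ggplot2::labs(x = NULL, y = "ReliefF weight")
}

#' Plot an estimated force trace
#'
#' @param trace Tibble from [estimate_force()] (columns `t`, `force`), or
#'   from [dynamic_force()] on a kinematic tibble (columns `time`, `force`).
#' @return A ggplot object.
#' @export
plot_force_trace <- function(trace) {
  tcol <- if ("t" %in% names(trace)) "t" else "time"
  ggplot2::ggplot(trace, ggplot2::aes(.data[[tcol]], .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (N)")
}
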