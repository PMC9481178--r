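#' Plot a simulated trajectory
#'
#' Ensemble-mean phosphorylation, structure, ADP occupancy and (optionally)
#' the windowed ADP release rate against time.
#'
#' @param object A `kai_trajectory`.
#' @param vars Columns to draw (default the four ensemble observables).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.kai_trajectory <- function(object,
                                    vars = c("D_mean", "X_mean", "q_mean",
                                             "qr"), ...) {
  df <- as.data.frame(object)[, c("t", vars)]
  long <- stats::reshape(df, direction = "long", varying = vars,
                         v.names = "value", timevar = "observable",
                         times = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scan result
#'
#' Period and amplitude against the scan variable; non-oscillatory points are
#' dropped from the period trace.
#'
#' @param object A `kai_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.kai_scan <- function(object, ...) {
  xvar <- attr(object, "scan_var") %||% names(object)[1]
  df <- as.data.frame(object)
  df_osc <- df[df$oscillatory, , drop = FALSE]
  ggplot2::ggplot(df_osc, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$period, colour = "period")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$period, colour = "period")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$amplitude * 24,
                                    colour = "amplitude")) +
    ggplot2::scale_y_continuous(
      name = "period (h)",
      sec.axis = ggplot2::sec_axis(~ . / 24, name = "amplitude")) +
    ggplot2::labs(x = xvar, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase-response curve
#'
#' @param object A `kai_prc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.kai_prc <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ct, y = .data$shift_ct_h)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$desynchronized)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "circadian time of onset (h)",
                  y = "phase shift (CT h, advance > 0)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kai_trajectory
#' @param traj A `kai_trajectory`.
#' @export
plot_trajectory <- function(traj, ...) autoplot.kai_trajectory(traj, ...)
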