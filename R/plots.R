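# ggplot2 autoplot methods. The cal BP axis is reversed so time runs
# forward (older -> younger) left to right.

scale_calbp <- function() {
  ggplot2::scale_x_reverse(name = "cal BP")
}

#' Plot an SCPD series
#'
#' @param object an `scpd_series`.
#' @param null optional null series (e.g. [taphonomic_null()] rescaled)
#'   overplotted in red.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scpd_series
#' @export
autoplot.scpd_series <- function(object, null = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp, y = .data$value)) +
    ggplot2::geom_line() +
    scale_calbp() +
    ggplot2::labs(y = "summed probability",
                  title = attr(object, "label"),
                  subtitle = sprintf("%s events", attr(object, "n_events")))
  if (!is.null(null)) {
    p <- p + ggplot2::geom_line(data = null, colour = "red")
  }
  p
}

#' Plot a smoothed series with its envelope
#'
#' @param object a `smoothed_series`.
#' @param series optional raw `scpd_series` underlay.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot smoothed_series
#' @export
autoplot.smoothed_series <- function(object, series = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25)
  }
  if (!is.null(series)) {
    p <- p + ggplot2::geom_line(
      data = series, ggplot2::aes(y = .data$value), colour = "grey60")
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    scale_calbp() + ggplot2::labs(y = "smoothed summed probability")
}

#' Plot cross-validation predictions against observations
#'
#' @param object a `mat_cv`.
#' @param ... unused.
#' @return a ggplot, one panel per climate variable.
#' @method autoplot mat_cv
#' @export
autoplot.mat_cv <- function(object, ...) {
  ps <- object$per_sample[!object$per_sample$depleted, ]
  long <- dplyr::bind_rows(
    tibble(variable = "t_summer", observed = ps$t_obs, predicted = ps$t_pred),
    tibble(variable = "p_summer", observed = ps$p_obs, predicted = ps$p_pred))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(title = sprintf("MAT %s cross-validation", object$mode))
}

#' Plot a regional climate anomaly curve
#'
#' @param object a `regional_curve`.
#' @param points optional pooled site points (tibble `cal_bp`, value in the
#'   fitted variable) underlaid.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot regional_curve
#' @export
autoplot.regional_curve <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    scale_calbp() +
    ggplot2::labs(y = sprintf("%s anomaly", attr(object, "variable")))
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(y = .data[[attr(object, "variable")]]),
      alpha = 0.4, size = 0.8)
  }
  p
}
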