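# SCPD construction and the null models applied to it.

new_scpd <- function(cal_bp, value, n_events, label = "SCPD") {
  out <- tibble(cal_bp = as.numeric(cal_bp), value = as.numeric(value))
  class(out) <- c("scpd_series", class(out))
  attr(out, "n_events") <- n_events
  attr(out, "label") <- label
  out
}

#' Pre-screen a radiocarbon dates table
#'
#' Applies the SCPD reliability filters: only measurements with a standard
#' deviation strictly below `sigma_max` (default 95 14C yr) and a context
#' class among `classes` are retained. A per-reason rejection count is
#' attached as the `"prescreen_report"` attribute.
#'
#' @param dates data frame with columns `sigma` and `context_class`.
#' @param sigma_max strict upper bound on the measurement error (14C yr).
#' @param classes context classes to keep.
#' @return the retained rows, with attribute `prescreen_report` (a tibble of
#'   counts: retained, rejected_sigma, rejected_class).
#' @export
prescreen_dates <- function(dates, sigma_max = 95,
                            classes = c("settlement", "funerary", "other")) {
  if (sigma_max <= 0) abort("sigma_max must be positive.")
  dates <- as_tibble(dates)
  check_dates_df(dates, c("sigma", "context_class"))
  bad_sigma <- !(dates$sigma < sigma_max)
  bad_class <- !(dates$context_class %in% classes)
  keep <- !bad_sigma & !bad_class
  report <- tibble(
    retained = sum(keep),
    rejected_sigma = sum(bad_sigma),
    rejected_class = sum(!bad_sigma & bad_class)
  )
  out <- dates[keep, , drop = FALSE]
  attr(out, "prescreen_report") <- report
  out
}

#' Sum calibrated densities into an SCPD series
#'
#' The Summed Calibrated Probability Distribution is the pointwise sum of
#' the (individually unit-mass) calibrated densities of the contributing
#' events; its total mass equals the number of events.
#'
#' @param events list of `cal_density` objects (1-yr grids).
#' @param window 2-vector of cal BP years; the output grid.
#' @param label series label carried into plots.
#' @return an `scpd_series` tibble (`cal_bp`, `value`) with attribute
#'   `n_events`.
#' @export
build_scpd <- function(events, window, label = "SCPD") {
  if (length(events) == 0L) abort("empty event list: nothing to sum.")
  grid <- window_grid(window)
  value <- numeric(length(grid))
  for (d in events) {
    idx <- match(d$cal_bp, grid)
    ok <- !is.na(idx)
    value[idx[ok]] <- value[idx[ok]] + d$mass[ok]
  }
  new_scpd(grid, value, n_events = length(events), label = label)
}

#' SCPD directly from an event-level dates table
#'
#' Convenience wrapper: calibrates each row of `dates` over `window` and
#' sums the densities. Rows are assumed to already be event-level (one row
#' per depositional event, e.g. the output of [combine_contexts()]).
#'
#' @inheritParams build_scpd
#' @param dates data frame with `c14_age`, `sigma`.
#' @param curve a `cal_curve`.
#' @export
scpd <- function(dates, curve, window, label = "SCPD") {
  dates <- as_tibble(dates)
  check_dates_df(dates)
  if (nrow(dates) == 0L) abort("empty dates table: nothing to sum.")
  grid <- window_grid(window)
  m <- calibrate_matrix(dates$c14_age, dates$sigma, curve, grid)
  new_scpd(grid, rowSums(m), n_events = nrow(dates), label = label)
}

#' Taphonomic-loss null model
#'
#' Power-law decay of the number of surviving datable contexts with age,
#' \deqn{n_t = a\,(t + b)^{-c}} with `t` in cal BP. The defaults are the
#' published global taphonomic correction parameters
#' (a = 5.726442e6, b = 2176.4 yr, c = 1.3925309).
#'
#' @param cal_bp calendar grid (years cal BP) on which to evaluate.
#' @param a,b,c power-law parameters; `a > 0`, `c > 0`, `t + b > 0`.
#' @param rescale_to optional `scpd_series` (or numeric total) whose total
#'   mass the null is rescaled to, for overplotting.
#' @return tibble `cal_bp`, `value`.
#' @export
taphonomic_null <- function(cal_bp, a = 5.726442e6, b = 2176.4, c = 1.3925309,
                            rescale_to = NULL) {
  if (a <= 0 || c <= 0) abort("a and c must be positive.")
  if (any(cal_bp + b <= 0)) abort("t + b must be positive over the grid.")
  value <- a * (cal_bp + b)^(-c)
  if (!is.null(rescale_to)) {
    target <- if (inherits(rescale_to, "scpd_series")) sum(rescale_to$value)
              else as.numeric(rescale_to)
    value <- value * target / sum(value)
  }
  tibble(cal_bp = as.numeric(cal_bp), value = value)
}

#' Simulated SCPD of uniformly distributed dates
#'
#' Null model for calibration-curve artefacts: assumes the same number of
#' dated contexts for every calendar year of the window. For each year
#' \eqn{\theta} a date with mean \eqn{\mu(\theta)} and error `sigma` is
#' calibrated and the densities are summed, so any structure in the result
#' (peaks at calendar-age steps, troughs at plateaus) is due to the curve
#' alone. By default the date means are set to \eqn{\mu(\theta)} exactly
#' (the construct is an expectation); with `noise = TRUE` means are drawn
#' from Normal(\eqn{\mu(\theta)}, \eqn{\sqrt{\sigma^2+\sigma_{curve}^2}}).
#'
#' @param curve a `cal_curve`.
#' @param window 2-vector cal BP.
#' @param dates_per_year dates simulated per calendar year (scales the
#'   series linearly).
#' @param sigma measurement error assigned to simulated dates (14C yr).
#' @param noise draw date means stochastically instead of deterministically.
#' @param seed optional integer seed used when `noise = TRUE`.
#' @return an `scpd_series`.
#' @export
simulate_uniform_scpd <- function(curve, window, dates_per_year = 1,
                                  sigma = 25, noise = FALSE, seed = NULL) {
  grid <- window_grid(window)
  at <- curve_at(curve, grid)
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    reps <- max(1L, as.integer(round(dates_per_year)))
    means <- rnorm(length(grid) * reps,
                   mean = rep(at$mu, reps),
                   sd = rep(sqrt(sigma^2 + at$sigma_curve^2), reps))
    m <- calibrate_matrix(means, rep(sigma, length(means)), curve, grid)
    value <- rowSums(m)
    n_ev <- length(means)
  } else {
    m <- calibrate_matrix(at$mu, rep(sigma, length(grid)), curve, grid)
    value <- rowSums(m) * dates_per_year
    n_ev <- length(grid) * dates_per_year
  }
  new_scpd(grid, value, n_events = n_ev, label = "simulated uniform SCPD")
}

#' Standardize a series to zero mean and unit variance
#'
#' Used to compare the empirical SCPD with the simulated uniform SCPD on a
#' common scale.
#'
#' @param series an `scpd_series` (or tibble with `cal_bp`, `value`).
#' @return the series with `value` replaced by its z-score.
#' @export
standardize_scpd <- function(series) {
  s <- sd(series$value)
  if (!is.finite(s) || s == 0) abort("degenerate series: zero variance.")
  out <- series
  out$value <- (series$value - mean(series$value)) / s
  out
}
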