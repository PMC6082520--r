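# LOWESS smoothing, bootstrap envelope, logistic neutral-growth test,
# linear baseline and excursion detection.

# Tricube local linear regression with bisquare robustification.
# Conventions (deliberately simple and fully documented so they can be
# recomputed independently):
#   * neighbourhood size r = min(n, max(3, floor(frac * n)))
#   * bandwidth at x_i = distance to its r-th nearest neighbour (self incl.)
#   * kernel weight (1 - min(d/h, 1)^3)^3, times robustness weights
#   * local fit: weighted least-squares line, evaluated at x_i; falls back
#     to the weighted mean when the local design is degenerate
#   * robustness: `iters` passes of bisquare weights (1 - (res/(6 m))^2)^2
#     for |res| < 6 m, m = median |residual|; skipped once m == 0
lowess_core <- function(x, y, frac, iters) {
  n <- length(x)
  r <- min(n, max(3L, floor(frac * n)))
  rob <- rep(1, n)
  fitted <- numeric(n)
  for (pass in seq_len(iters + 1L)) {
    lo <- 1L; hi <- r
    for (i in seq_len(n)) {
      # slide the contiguous window of r points nearest to x[i]
      while (hi < n && (x[hi + 1L] - x[i]) < (x[i] - x[lo])) {
        lo <- lo + 1L; hi <- hi + 1L
      }
      d <- abs(x[lo:hi] - x[i])
      h <- max(d)
      u <- if (h > 0) pmin(d / h, 1) else rep(0, length(d))
      w <- (1 - u^3)^3 * rob[lo:hi]
      sw <- sum(w)
      if (sw <= 0) { fitted[i] <- y[i]; next }
      xx <- x[lo:hi]; yy <- y[lo:hi]
      xbar <- sum(w * xx) / sw
      vx <- sum(w * (xx - xbar)^2)
      if (vx <= 1e-12 * (x[n] - x[1])^2) {
        fitted[i] <- sum(w * yy) / sw
      } else {
        b <- sum(w * (xx - xbar) * yy) / vx
        a <- sum(w * yy) / sw - b * xbar
        fitted[i] <- a + b * x[i]
      }
    }
    if (pass > iters) break
    res <- y - fitted
    m <- median(abs(res))
    if (m == 0) break
    rob <- pmax(0, 1 - (res / (6 * m))^2)^2
  }
  fitted
}

new_smoothed <- function(cal_bp, fitted, lower = NULL, upper = NULL,
                         reps = NULL) {
  out <- tibble(cal_bp = as.numeric(cal_bp), fitted = as.numeric(fitted))
  if (!is.null(lower)) { out$lower <- lower; out$upper <- upper }
  class(out) <- c("smoothed_series", class(out))
  attr(out, "reps") <- reps
  out
}

#' LOWESS smoothing of an SCPD series
#'
#' Locally weighted scatterplot smoothing: a weighted linear fit with
#' tricube kernel weights in a sliding neighbourhood containing a fraction
#' `frac` of the points, robustified by `iters` bisquare reweighting passes.
#' Applied to SCPD series to damp the spurious peaks and troughs induced by
#' the slope of the calibration curve. Degree-1 local fits reproduce exactly
#' linear series exactly.
#'
#' @param series tibble with `cal_bp` and `value` (an `scpd_series`).
#' @param frac span: fraction of points in each local neighbourhood
#'   (default 0.1).
#' @param iters robustness iterations (default 2).
#' @return a `smoothed_series` tibble (`cal_bp`, `fitted`).
#' @export
lowess_smooth <- function(series, frac = 0.1, iters = 2) {
  if (frac <= 0 || frac > 1) abort("frac must be in (0, 1].")
  n <- nrow(series)
  if (n < 4L || floor(frac * n) < 2L) {
    abort("too few points for the requested span.")
  }
  new_smoothed(series$cal_bp,
               lowess_core(series$cal_bp, series$value, frac, iters))
}

#' Bootstrap confidence envelope for a smoothed SCPD
#'
#' Generates `reps` simulated datasets, each with `n_events` calendar ages
#' drawn uniformly over the window (the no-demographic-change null), back-
#' mapped through the calibration curve with measurement errors resampled
#' from the empirical error pool, calibrated, summed and LOWESS-smoothed.
#' The pointwise 2.5/97.5 percentiles across replicates form the 95%
#' envelope of "possible demographic histories"; `fitted` is the pointwise
#' replicate mean.
#'
#' @param curve a `cal_curve`.
#' @param window 2-vector cal BP.
#' @param n_events number of events per replicate (match the empirical
#'   event count).
#' @param sigma_pool numeric vector of measurement errors to resample
#'   (e.g. the screened dataset's sigmas).
#' @param reps bootstrap replicates (default 500).
#' @param frac,iters LOWESS parameters, as in [lowess_smooth()].
#' @param seed integer seed; same seed gives an identical envelope.
#' @return a `smoothed_series` with `lower` and `upper` columns and
#'   attribute `reps`.
#' @export
bootstrap_envelope <- function(curve, window, n_events, sigma_pool,
                               reps = 500, frac = 0.1, iters = 2,
                               seed = NULL) {
  if (reps < 2) abort("reps must be at least 2.")
  if (n_events < 1) abort("n_events must be at least 1.")
  if (!length(sigma_pool) || any(sigma_pool <= 0)) {
    abort("sigma_pool must be a non-empty vector of positive errors.")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- window_grid(window)
  at <- curve_at(curve, grid)
  sims <- matrix(NA_real_, nrow = length(grid), ncol = reps)
  for (b in seq_len(reps)) {
    j <- sample.int(length(grid), n_events, replace = TRUE)
    sig <- sample(sigma_pool, n_events, replace = TRUE)
    means <- rnorm(n_events, at$mu[j], sqrt(sig^2 + at$sigma_curve[j]^2))
    value <- rowSums(calibrate_matrix(means, sig, curve, grid))
    sims[, b] <- lowess_core(grid, value, frac, iters)
  }
  # order-statistic (type 1) quantiles: with 2 reps the envelope is the
  # min/max of the replicate curves
  lower <- apply(sims, 1, quantile, probs = 0.025, type = 1)
  upper <- apply(sims, 1, quantile, probs = 0.975, type = 1)
  new_smoothed(grid, rowMeans(sims), lower, upper, reps = reps)
}

series_values <- function(series) {
  if ("fitted" %in% names(series)) series$fitted else series$value
}

#' Fit a logistic neutral-growth model
#'
#' The null hypothesis of neutral population growth is a standard logistic
#' \deqn{N(t) = K / (1 + e^{-r (t - t_0)})}
#' fitted by least squares on the calendar-forward axis (years AD, negative
#' values = BC), typically to the LOWESS-smoothed SCPD. Initial values are
#' K = max(y), t0 at the half-maximum crossing and r from the local slope
#' there; five jittered restarts are attempted before failure is declared.
#'
#' @param series tibble with `cal_bp` and `fitted` (or `value`); at least
#'   4 points.
#' @param restarts number of jittered restarts.
#' @return a `logistic_fit` object; see [tidy()] and [glance()] methods.
#'   Fields: `K` (carrying capacity, probability units), `r` (growth per
#'   year), `t0` (inflection, calendar-forward year), `t0_cal_bp`, `rss`.
#' @export
fit_logistic <- function(series, restarts = 5) {
  y <- series_values(series)
  t <- cal_forward(series$cal_bp)
  if (length(y) < 4L) abort("fit_logistic needs at least 4 points.")
  o <- order(t)
  t <- t[o]; y <- y[o]
  K0 <- max(y)
  half <- K0 / 2
  cross <- which(diff(sign(y - half)) != 0)
  t00 <- if (length(cross)) t[cross[1]] else t[which.min(abs(y - half))]
  i0 <- which.min(abs(t - t00))
  i1 <- min(length(t), i0 + max(1L, length(t) %/% 20))
  i2 <- max(1L, i0 - max(1L, length(t) %/% 20))
  slope0 <- (y[i1] - y[i2]) / (t[i1] - t[i2])
  r0 <- 4 * slope0 / K0
  if (!is.finite(r0) || abs(r0) < 1e-8) r0 <- 1e-8
  dat <- data.frame(t = t, y = y)
  # deterministic restart grid: scaled K/r and shifted t0
  k_fac <- c(1, 1.5, 0.75, 2, 1, 1.25)
  r_fac <- c(1, 0.5, 2, 0.1, 5, 1)
  t_off <- c(0, 0, 0, 1, -1, 0.5) * diff(range(t)) / 8
  starts <- lapply(seq_len(min(restarts + 1L, length(k_fac))), function(i) {
    list(K = K0 * k_fac[i], r = r0 * r_fac[i], t0 = t00 + t_off[i])
  })
  best <- NULL; errors <- character()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ K / (1 + exp(-r * (t - t0))),
                        data = dat, start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { errors <- c(errors, conditionMessage(fit)); next }
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort(paste0("logistic fit failed after restarts: ",
                 paste(unique(errors), collapse = "; ")))
  }
  cf <- coef(best$fit)
  if (cf[["K"]] <= 0) abort("logistic fit returned non-positive K.")
  structure(list(
    K = unname(cf["K"]), r = unname(cf["r"]), t0 = unname(cf["t0"]),
    t0_cal_bp = 1950 - unname(cf["t0"]), rss = best$rss, n = length(y),
    data = tibble(cal_bp = 1950 - t, observed = y,
                  fitted = predict(best$fit))
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic neutral-growth fit\n")
  cat(sprintf("  K  = %.6g\n  r  = %.6g per yr\n  t0 = %.1f cal BP\n  rss = %.6g (n = %d)\n",
              x$K, x$r, x$t0_cal_bp, x$rss, x$n))
  invisible(x)
}

#' Tidy a logistic neutral-growth fit
#' @param x a `logistic_fit`.
#' @param ... unused.
#' @return tibble of parameter estimates.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("K", "r", "t0"),
         estimate = c(x$K, x$r, x$t0))
}

#' @rdname tidy.logistic_fit
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(K = x$K, r = x$r, t0_cal_bp = x$t0_cal_bp, rss = x$rss, n = x$n)
}

#' Linear trend baseline of a series
#'
#' Ordinary least squares of the series values on the calendar-forward
#' axis. The fitted line is the baseline against which peaks and valleys
#' are read; residuals are returned alongside.
#'
#' @param series tibble with `cal_bp` and `value` (or `fitted`).
#' @return a `linear_trend` tibble (`cal_bp`, `value`, `trend`, `residual`)
#'   with attributes `slope` (per calendar-forward year) and `intercept`;
#'   see [glance()].
#' @export
linear_trend <- function(series) {
  y <- series_values(series)
  if (length(y) < 2L) abort("linear_trend needs at least 2 points.")
  t <- cal_forward(series$cal_bp)
  fit <- lm(y ~ t)
  out <- tibble(cal_bp = series$cal_bp, value = y,
                trend = unname(fitted(fit)),
                residual = unname(residuals(fit)))
  class(out) <- c("linear_trend", class(out))
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "intercept") <- unname(coef(fit)[1])
  out
}

#' @rdname linear_trend
#' @param x a `linear_trend`.
#' @param ... unused.
#' @method glance linear_trend
#' @export
glance.linear_trend <- function(x, ...) {
  tss <- sum((x$value - mean(x$value))^2)
  tibble(slope = attr(x, "slope"), intercept = attr(x, "intercept"),
         r_squared = if (tss > 0) 1 - sum(x$residual^2) / tss else NA_real_,
         n = nrow(x))
}

#' Detect excursions of a series above/below a reference
#'
#' Finds maximal runs of at least `min_run` consecutive years in which the
#' series lies strictly above or strictly below the reference. The
#' reference is either a baseline (numeric vector or a tibble carrying
#' `trend`/`fitted`/`value`) or a bootstrap envelope (`lower`/`upper`
#' columns), in which case "above" means above `upper` and "below" means
#' below `lower`.
#'
#' @param series tibble with `cal_bp` and `value` (or `fitted`).
#' @param reference numeric vector on the same grid, or a tibble as above.
#' @param min_run minimum excursion length in years (default 30).
#' @return tibble `start_cal_bp` (older bound), `end_cal_bp`, `sign`
#'   ("above"/"below"), `run_years`, oldest excursion first.
#' @export
detect_excursions <- function(series, reference, min_run = 30) {
  y <- series_values(series)
  if (is.data.frame(reference) && all(c("lower", "upper") %in% names(reference))) {
    state <- ifelse(y > reference$upper, 1L, ifelse(y < reference$lower, -1L, 0L))
  } else {
    ref <- if (is.numeric(reference)) reference
           else if ("trend" %in% names(reference)) reference$trend
           else series_values(reference)
    if (length(ref) != length(y)) abort("reference not on the series grid.")
    state <- ifelse(y > ref, 1L, ifelse(y < ref, -1L, 0L))
  }
  step <- if (nrow(series) > 1) abs(diff(series$cal_bp[1:2])) else 1
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths * step >= min_run
  out <- tibble(
    start_cal_bp = pmax(series$cal_bp[starts[keep]], series$cal_bp[ends[keep]]),
    end_cal_bp = pmin(series$cal_bp[starts[keep]], series$cal_bp[ends[keep]]),
    sign = ifelse(r$values[keep] > 0, "above", "below"),
    run_years = r$lengths[keep] * step
  )
  dplyr::arrange(out, dplyr::desc(.data$start_cal_bp))
}
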