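# Age-depth models, anomaly expression, windowed site series and the
# weighted regional LOESS synthesis.

#' Classical linear-interpolation age-depth model
#'
#' Builds a piecewise-linear age(depth) model from dated control points
#' (the classical age-model construction, with control ages taken as the
#' weighted means of their calibrated densities). The 1-sigma dating error
#' is interpolated linearly between controls as well. Depths must be
#' strictly monotone and ages non-decreasing with depth; reversals are
#' rejected naming the offending pair. No extrapolation beyond the
#' outermost controls by default.
#'
#' @param control_points data frame `depth` (cm), `age` (cal BP),
#'   `age_sigma` (yr); at least 2 rows.
#' @return an `age_model` object.
#' @export
age_model <- function(control_points) {
  cp <- as_tibble(control_points)
  need <- c("depth", "age", "age_sigma")
  if (!all(need %in% names(cp))) {
    abort("control points need columns depth, age, age_sigma.")
  }
  if (nrow(cp) < 2L) abort("an age model needs at least 2 control points.")
  cp <- dplyr::arrange(cp, .data$depth)
  if (anyDuplicated(cp$depth)) abort("control depths must be strictly monotone.")
  rev_idx <- which(diff(cp$age) < 0)
  if (length(rev_idx)) {
    abort(sprintf("age reversal between depths %g and %g cm (%g -> %g cal BP).",
                  cp$depth[rev_idx[1]], cp$depth[rev_idx[1] + 1],
                  cp$age[rev_idx[1]], cp$age[rev_idx[1] + 1]))
  }
  structure(list(control_points = cp), class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Linear age-depth model, %d control points, %g-%g cm / %g-%g cal BP\n",
              nrow(x$control_points), min(x$control_points$depth),
              max(x$control_points$depth), min(x$control_points$age),
              max(x$control_points$age)))
  invisible(x)
}

#' Predict ages (and interpolated dating errors) at depths
#'
#' @param object an [age_model()].
#' @param depth depths (cm) to date.
#' @param extrapolate allow queries beyond the outermost controls
#'   (default FALSE: out-of-range depths are an error).
#' @param ... unused.
#' @return tibble `depth`, `age` (cal BP), `age_sigma`.
#' @export
predict.age_model <- function(object, depth, extrapolate = FALSE, ...) {
  cp <- object$control_points
  rng <- range(cp$depth)
  if (!extrapolate && any(depth < rng[1] | depth > rng[2])) {
    abort(sprintf("depth outside dated range [%g, %g] cm and extrapolation is off.",
                  rng[1], rng[2]))
  }
  rule <- if (extrapolate) 2 else 1
  tibble(depth = as.numeric(depth),
         age = approx(cp$depth, cp$age, xout = depth, rule = rule)$y,
         age_sigma = approx(cp$depth, cp$age_sigma, xout = depth, rule = rule)$y)
}

#' Distance in years to the nearest dated control point
#'
#' Used to mask reconstruction windows more than a cutoff (1000 yr in the
#' default configuration) away from the closest radiocarbon-dated point of
#' a core.
#'
#' @param model an [age_model()].
#' @param age ages (cal BP), vectorized.
#' @return years to the nearest control age.
#' @export
dating_distance <- function(model, age) {
  stopifnot(inherits(model, "age_model"))
  vapply(age, function(a) min(abs(a - model$control_points$age)), 0)
}

#' Express reconstructions as anomalies from a reference window
#'
#' Subtracts, per variable and per group (region by default, pooled over
#' the group's sites), the mean of all values dated inside the reference
#' window. The output is mean-zero over the window within each group.
#'
#' @param df data frame with an age column and the value columns.
#' @param vars value columns to convert (default `t_summer`, `p_summer`).
#' @param age_col name of the cal BP age column.
#' @param window 2-vector cal BP reference window (default 2750-3750,
#'   i.e. 1800-800 BC).
#' @param group optional grouping column name (e.g. `"region"`); NULL
#'   treats the whole table as one group.
#' @return `df` with the value columns replaced by anomalies.
#' @export
to_anomalies <- function(df, vars = c("t_summer", "p_summer"),
                         age_col = "cal_bp", window = c(2750, 3750),
                         group = NULL) {
  df <- as_tibble(df)
  w <- sort(window)
  groups <- if (is.null(group)) rep(1L, nrow(df)) else df[[group]]
  for (g in unique(groups)) {
    rows <- which(groups == g)
    in_win <- rows[df[[age_col]][rows] >= w[1] & df[[age_col]][rows] <= w[2] &
                     !is.na(df[[age_col]][rows])]
    if (!length(in_win)) {
      abort(sprintf("no values inside the reference window for group '%s'.", g))
    }
    for (v in vars) {
      ref <- mean(df[[v]][in_win], na.rm = TRUE)
      df[[v]][rows] <- df[[v]][rows] - ref
    }
  }
  df
}

#' Average dated reconstructions into overlapping windows
#'
#' Bins per-sample reconstructions into overlapping windows of `width`
#' years centred every `step` years (defaults 100/50). Window membership is
#' half-open, `[centre - width/2, centre + width/2)`, so a sample at an
#' overlap boundary is counted once. The window value is the member mean;
#' the window weight is the inverse of the members' mean dating error
#' (capped at 10x the series median to keep exact control hits finite).
#' Windows with no members -- or, when an age model is supplied, windows
#' farther than `max_dating_distance` from the nearest dated control --
#' are masked (`quality = FALSE`).
#'
#' @param samples data frame with `age` (cal BP), `age_sigma` (yr) and the
#'   value columns.
#' @param vars value columns to average.
#' @param width,step window span and increment in years.
#' @param model optional [age_model()] used for the dating-distance mask.
#' @param max_dating_distance mask cutoff in years (default 1000).
#' @param centres optional explicit window-centre grid (cal BP).
#' @return a `site_series` tibble: `cal_bp` (centre), value columns,
#'   `weight`, `n`, `quality`.
#' @export
window_average <- function(samples, vars = c("t_summer", "p_summer"),
                           width = 100, step = 50, model = NULL,
                           max_dating_distance = 1000, centres = NULL) {
  if (width <= 0 || step <= 0) abort("width and step must be positive.")
  samples <- as_tibble(samples)
  if (is.null(centres)) {
    lo <- floor(min(samples$age) / step) * step
    hi <- ceiling(max(samples$age) / step) * step
    centres <- seq(lo, hi, by = step)
  }
  rows <- lapply(centres, function(ct) {
    inw <- samples$age >= ct - width / 2 & samples$age < ct + width / 2
    out <- tibble(cal_bp = ct, n = sum(inw))
    for (v in vars) out[[v]] <- if (any(inw)) mean(samples[[v]][inw]) else NA_real_
    out$mean_sigma <- if (any(inw)) mean(samples$age_sigma[inw]) else NA_real_
    out
  })
  out <- bind_rows(rows)[, c("cal_bp", vars, "mean_sigma", "n")]
  out$quality <- out$n > 0
  if (!is.null(model)) {
    out$quality <- out$quality &
      dating_distance(model, out$cal_bp) <= max_dating_distance
  }
  w <- ifelse(out$mean_sigma > 0, 1 / out$mean_sigma, Inf)
  med <- median(w[is.finite(w) & out$quality], na.rm = TRUE)
  cap <- if (is.finite(med)) 10 * med else 1
  out$weight <- pmin(w, cap)
  out$mean_sigma <- NULL
  class(out) <- c("site_series", class(out))
  out
}

#' Weighted regional LOESS synthesis
#'
#' Pools the unmasked windowed values of every site in a region and fits a
#' degree-1 LOESS curve of anomaly against window centre, with the windows'
#' inverse-dating-error weights as observation weights. The 95% band is the
#' parametric fitted value plus/minus 1.96 pointwise standard errors. With
#' small datasets the span is floored so each local fit sees at least 4
#' points.
#'
#' @param site_series list of `site_series` tibbles (or one pooled tibble),
#'   each with a `site_id` column or named list entries.
#' @param var value column to fit.
#' @param span LOESS span (default 0.06, fraction of pooled points).
#' @param grid evaluation grid in cal BP (default: the pooled window
#'   centres).
#' @return a `regional_curve` tibble: `cal_bp`, `fitted`, `lower`, `upper`,
#'   `n_sites` (sites with an unmasked window within 100 yr of the grid
#'   point).
#' @export
regional_loess <- function(site_series, var = "t_summer", span = 0.06,
                           grid = NULL) {
  if (is.data.frame(site_series)) site_series <- list(site_series)
  if (is.null(names(site_series))) {
    names(site_series) <- vapply(seq_along(site_series), function(i) {
      s <- site_series[[i]]
      if ("site_id" %in% names(s)) as.character(s$site_id[1]) else paste0("site", i)
    }, "")
  }
  pooled <- bind_rows(lapply(names(site_series), function(nm) {
    s <- site_series[[nm]]
    tibble(site = nm, cal_bp = s$cal_bp, value = s[[var]],
           weight = s$weight, quality = s$quality)
  }))
  pooled <- pooled[pooled$quality & !is.na(pooled$value), , drop = FALSE]
  n <- nrow(pooled)
  if (n < 4L) abort("fewer than 4 unmasked points: cannot fit a regional curve.")
  # floor the span so each local fit spans >= 4 distinct window centres
  # (several sites share centres; distinct abscissae keep degree-1 fits
  # well-conditioned)
  n_distinct <- length(unique(pooled$cal_bp))
  span_eff <- max(span, min(1, 4 / n_distinct))
  fit <- loess(value ~ cal_bp, data = pooled, weights = pooled$weight,
               span = span_eff, degree = 1, family = "gaussian",
               surface = "direct")
  if (is.null(grid)) grid <- sort(unique(pooled$cal_bp))
  pr <- predict(fit, newdata = data.frame(cal_bp = grid), se = TRUE)
  n_sites <- vapply(grid, function(g) {
    length(unique(pooled$site[abs(pooled$cal_bp - g) <= 100]))
  }, 0L)
  out <- tibble(cal_bp = grid, fitted = as.numeric(pr$fit),
                lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
                upper = as.numeric(pr$fit + 1.96 * pr$se.fit),
                n_sites = n_sites)
  class(out) <- c("regional_curve", class(out))
  attr(out, "span") <- span_eff
  attr(out, "variable") <- var
  out
}
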