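# Calibration-curve handling and single-date calibration.

new_cal_curve <- function(cal_bp, c14_age, error, name = "curve") {
  out <- tibble(cal_bp = as.numeric(cal_bp),
                c14_age = as.numeric(c14_age),
                error = as.numeric(error))
  out <- dplyr::arrange(out, .data$cal_bp)
  class(out) <- c("cal_curve", class(out))
  attr(out, "curve_name") <- name
  out
}

#' Build a calibration curve from node vectors
#'
#' A calibration curve maps a calendar age \eqn{\theta} (cal BP) to an
#' expected radiocarbon age \eqn{\mu(\theta)} with a 1-sigma curve error
#' \eqn{\sigma_{curve}(\theta)}. Between nodes both quantities are linearly
#' interpolated.
#'
#' @param cal_bp calendar ages of the nodes (years cal BP), any order but
#'   strictly monotone once sorted.
#' @param c14_age radiocarbon age at each node (14C yr BP).
#' @param error 1-sigma curve error at each node (14C yr), all positive.
#' @param name label carried through outputs.
#' @return a `cal_curve` tibble with columns `cal_bp`, `c14_age`, `error`,
#'   sorted ascending in `cal_bp`.
#' @seealso [read_calibration_curve()], [make_calibration_curve()]
#' @export
calibration_curve <- function(cal_bp, c14_age, error, name = "curve") {
  if (!(length(cal_bp) == length(c14_age) && length(cal_bp) == length(error))) {
    abort("cal_bp, c14_age and error must have equal length.")
  }
  if (length(cal_bp) < 2L) abort("a calibration curve needs at least 2 nodes.")
  if (anyDuplicated(cal_bp)) abort("cal_bp grid must be strictly monotone.")
  if (any(error <= 0)) abort("curve error must be positive everywhere.")
  new_cal_curve(cal_bp, c14_age, error, name)
}

#' Read a calibration curve in IntCal text format
#'
#' IntCal-style files carry `#`-prefixed header lines followed by
#' comma-separated rows `CAL BP, 14C age, Error[, Delta14C, Sigma]`. Extra
#' columns are ignored. Rows may be in descending cal BP order; the returned
#' curve is always sorted ascending.
#'
#' @param path path to the curve file (or a connection).
#' @param name curve label; defaults to the file name.
#' @return a `cal_curve` tibble.
#' @export
read_calibration_curve <- function(path, name = NULL) {
  lines <- readLines(path)
  if (is.null(name)) name <- if (is.character(path)) basename(path) else "curve"
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (length(data_lines) < 2L) {
    abort("insufficient calibration curve: fewer than 2 data rows.")
  }
  rows <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(data_lines[[i]], ",")[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("malformed curve row on data line %d: need >= 3 columns.", i))
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (any(is.na(vals))) {
      abort(sprintf("malformed curve row on data line %d: non-numeric field.", i))
    }
    vals
  })
  m <- do.call(rbind, rows)
  calibration_curve(m[, 1], m[, 2], m[, 3], name = name)
}

#' Evaluate a calibration curve at calendar ages
#'
#' Returns the interpolated radiocarbon age and curve error at arbitrary
#' calendar ages within the curve support. Values at nodes are exact; between
#' nodes both mu and the error are linearly interpolated.
#'
#' @param curve a `cal_curve`.
#' @param cal_bp calendar ages (years cal BP) to query.
#' @return tibble with columns `cal_bp`, `mu`, `sigma_curve`.
#' @export
curve_at <- function(curve, cal_bp) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1] | cal_bp > rng[2])) {
    abort(sprintf("query outside curve support [%g, %g] cal BP.", rng[1], rng[2]))
  }
  tibble(
    cal_bp = as.numeric(cal_bp),
    mu = approx(curve$cal_bp, curve$c14_age, xout = cal_bp)$y,
    sigma_curve = approx(curve$cal_bp, curve$error, xout = cal_bp)$y
  )
}

# Vectorized calibration of many dates sharing one grid. Returns a
# grid x n matrix, each column the (optionally normalized) likelihood
# exp(-(x - mu)^2 / (2 (sigma^2 + sigma_curve^2))) evaluated per year.
calibrate_matrix <- function(c14_age, sigma, curve, grid, normalize = TRUE) {
  at <- curve_at(curve, grid)
  var_grid <- outer(at$sigma_curve^2, sigma^2, "+")
  dev <- outer(at$mu, c14_age, "-")
  m <- exp(-dev^2 / (2 * var_grid))
  if (normalize) {
    tot <- colSums(m)
    if (any(tot < 1e-12)) {
      abort("degenerate density: date incompatible with the analysis window.")
    }
    m <- sweep(m, 2, tot, "/")
  }
  m
}

#' Calibrate a single radiocarbon determination
#'
#' Evaluates the standard calibration likelihood
#' \deqn{p(\theta) \propto \exp\{-(x - \mu(\theta))^2 /
#'   (2(\sigma^2 + \sigma_{curve}(\theta)^2))\}}
#' on a 1-year calendar grid over `window` and normalizes it to unit mass
#' over that window.
#'
#' @param c14_age measured radiocarbon age (14C yr BP).
#' @param sigma 1-sigma measurement error (14C yr), positive.
#' @param curve a `cal_curve`.
#' @param window 2-vector of cal BP years bounding the analysis window,
#'   inside the curve support.
#' @return a `cal_density` tibble with columns `cal_bp`, `mass`
#'   (summing to 1) and attribute `n_measurements = 1`.
#' @examples
#' crv <- calibration_curve(cal_bp = c(2000, 4000),
#'                          c14_age = c(2000, 4000), error = c(1e-6, 1e-6))
#' d <- calibrate_date(3000, 30, crv, window = c(2500, 3500))
#' sum(d$mass)
#' @export
calibrate_date <- function(c14_age, sigma, curve, window) {
  stopifnot(length(c14_age) == 1L, length(sigma) == 1L)
  if (sigma <= 0) abort("sigma must be positive.")
  grid <- window_grid(window)
  rng <- range(curve$cal_bp)
  if (grid[1] < rng[1] || grid[length(grid)] > rng[2]) {
    abort("analysis window outside curve support.")
  }
  mass <- calibrate_matrix(c14_age, sigma, curve, grid)[, 1]
  out <- tibble(cal_bp = grid, mass = mass)
  class(out) <- c("cal_density", class(out))
  attr(out, "n_measurements") <- 1L
  out
}
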