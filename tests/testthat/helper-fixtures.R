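# Shared fixtures and independent oracles, built in code.

# identity calibration curve: mu(theta) = theta, tiny constant error so the
# calibrated density approaches the closed-form Gaussian limit
identity_curve <- function(from = 2000, to = 5000, error = 1e-9) {
  make_calibration_curve(
    data.frame(from_bp = from, to_bp = to, slope = 1),
    c14_start = from, error_level = error, node_step = 50,
    name = "identity")
}

# smooth near-identity curve with realistic error, for simulations
smooth_curve <- function(from = 2000, to = 5000, error = 10) {
  make_calibration_curve(
    data.frame(from_bp = from, to_bp = to, slope = 1),
    c14_start = from, error_level = error, node_step = 5,
    name = "smooth")
}

make_dates <- function(c14_age, sigma, site_id = "S1",
                       context_id = paste0("C", seq_along(c14_age)),
                       context_class = "settlement", region = "R1") {
  tibble::tibble(
    lab_id = paste0("L", seq_along(c14_age)),
    site_id = site_id, context_id = context_id,
    context_class = context_class,
    c14_age = c14_age, sigma = sigma, region = region,
    lat = NA_real_, lon = NA_real_)
}

# Independent LOWESS oracle: same documented conventions as lowess_smooth
# (r-th-nearest bandwidth, tricube kernel, bisquare robustness) but computed
# naively per point through lm().
oracle_lowess <- function(x, y, frac, iters) {
  n <- length(x)
  r <- min(n, max(3L, floor(frac * n)))
  rob <- rep(1, n)
  fit <- numeric(n)
  for (pass in seq_len(iters + 1L)) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      h <- sort(d)[r]
      w <- (1 - pmin(d / h, 1)^3)^3 * rob
      fit[i] <- unname(predict(lm(y ~ x, weights = w),
                               newdata = data.frame(x = x[i])))
    }
    if (pass > iters) break
    res <- y - fit
    m <- median(abs(res))
    if (m == 0) break
    rob <- pmax(0, 1 - (res / (6 * m))^2)^2
  }
  fit
}

default_response <- function(count_total = 500) {
  example_response_spec(count_total)
}

build_training_from_set <- function(ts) {
  props <- pft_proportions(ts$counts, ts$mapping, ts$terrestrial)
  mat_training(props, ts$climate, ts$metadata[, c("sample_id", "lat", "lon")])
}
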