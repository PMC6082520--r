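# SCPD construction, null models, smoothing, growth tests, excursions.

test_that("prescreening applies the strict error cutoff and class filter", {
  d <- make_dates(rep(3000, 10), c(30, 40, 50, 60, 70, 80, 90, 95, 100, 120),
                  context_class = rep(c("settlement", "funerary"), 5))
  kept <- prescreen_dates(d, sigma_max = 95)
  expect_equal(nrow(kept), 7L)               # sigma = 95 excluded, strict <
  expect_true(all(kept$sigma < 95))
  rep1 <- attr(kept, "prescreen_report")
  expect_equal(rep1$rejected_sigma, 3L)

  only_settl <- prescreen_dates(d, sigma_max = 95, classes = "settlement")
  expect_true(all(only_settl$context_class == "settlement"))
  expect_equal(nrow(only_settl), 4L)
  expect_equal(attr(only_settl, "prescreen_report")$rejected_class, 3L)
})

test_that("SCPD is the pointwise sum of unit-mass densities", {
  crv <- smooth_curve()
  w <- c(2500, 3500)
  d1 <- calibrate_date(2800, 25, crv, w)
  d2 <- calibrate_date(3200, 25, crv, w)

  one <- build_scpd(list(d1), w)
  expect_equal(one$value, d1$mass)
  expect_equal(attr(one, "n_events"), 1L)

  both <- build_scpd(list(d1, d2), w)
  expect_equal(sum(both$value), 2, tolerance = 1e-6)
  # disjoint narrow densities give a bimodal series
  peaks <- both$cal_bp[order(both$value, decreasing = TRUE)[1:2]]
  expect_true(any(abs(peaks - 2800) < 50) && any(abs(peaks - 3200) < 50))

  expect_error(build_scpd(list(), w), "empty")
})

test_that("scpd() conserves mass and is additive over event sets", {
  crv <- smooth_curve()
  w <- c(2400, 3600)
  set.seed(3)
  d <- make_dates(runif(40, 2700, 3300), runif(40, 20, 60))
  s_all <- scpd(d, crv, w)
  expect_equal(sum(s_all$value), 40, tolerance = 1e-6)
  expect_true(all(s_all$value >= 0))
  # linearity: concatenated event sets sum to the sum of their SCPDs
  s_a <- scpd(d[1:15, ], crv, w)
  s_b <- scpd(d[16:40, ], crv, w)
  expect_equal(s_all$value, s_a$value + s_b$value, tolerance = 1e-12)
})

test_that("SCPD recovers the modes of a bimodal event density", {
  crv <- smooth_curve()
  spec <- event_density_spec(
    "mixture",
    params = data.frame(mean_bp = c(2900, 3300), sd = c(40, 40),
                        weight = c(1, 1)),
    window = c(2600, 3600))
  d <- simulate_dates(spec, crv, n_contexts = 200, sigma = 20, seed = 11)
  s <- scpd(d, crv, c(2600, 3600))
  left <- s[s$cal_bp < 3100, ]
  right <- s[s$cal_bp >= 3100, ]
  expect_lt(abs(left$cal_bp[which.max(left$value)] - 2900), 30)
  expect_lt(abs(right$cal_bp[which.max(right$value)] - 3300), 30)
})

test_that("taphonomic null matches direct evaluation and decays into the past", {
  grid <- 2750:3750
  null <- taphonomic_null(grid)
  direct <- 5.726442e6 * (grid + 2176.4)^(-1.3925309)
  expect_equal(null$value, direct)               # elementwise oracle
  expect_true(all(diff(null$value) < 0))         # strictly decreasing in cal BP
  expect_gt(null$value[null$cal_bp == 2750], null$value[null$cal_bp == 3750])

  expect_equal(taphonomic_null(2, a = 1, b = 0, c = 1)$value, 0.5)
  expect_error(taphonomic_null(-3000, a = 1, b = 0, c = 1), "positive")

  rescaled <- taphonomic_null(grid, rescale_to = 852)
  expect_equal(sum(rescaled$value), 852, tolerance = 1e-9)
})

test_that("uniform simulated SCPD is flat on a featureless curve and linear in rate", {
  crv <- smooth_curve(2000, 5000)
  s <- simulate_uniform_scpd(crv, c(2800, 3800), sigma = 20)
  interior <- s$value[s$cal_bp >= 2900 & s$cal_bp <= 3700]
  expect_lt(sd(interior) / mean(interior), 0.05)

  s2 <- simulate_uniform_scpd(crv, c(2800, 3800), dates_per_year = 2, sigma = 20)
  expect_equal(s2$value, 2 * s$value, tolerance = 1e-12)

  # same seed twice with noise -> identical
  n1 <- simulate_uniform_scpd(crv, c(2800, 3800), sigma = 20, noise = TRUE, seed = 5)
  n2 <- simulate_uniform_scpd(crv, c(2800, 3800), sigma = 20, noise = TRUE, seed = 5)
  expect_equal(n1$value, n2$value)
})

test_that("a calendar-age step produces a local peak in the simulated SCPD", {
  crv <- make_calibration_curve(
    data.frame(from_bp = c(2700, 2990, 3010),
               to_bp   = c(2990, 3010, 3300),
               slope   = c(1, 15, 1)),
    c14_start = 2700, error_level = 10, node_step = 5)
  s <- simulate_uniform_scpd(crv, c(2700, 3300), sigma = 25)
  v <- s$value
  n <- length(v)
  is_locmax <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
                 FALSE)
  locmax_bp <- s$cal_bp[is_locmax]
  expect_lte(min(abs(locmax_bp - 3000)), 25)
  # and the step's local maximum rises clearly above the flanking troughs
  spike <- max(v[abs(s$cal_bp - 3000) <= 25])
  trough <- min(v[abs(s$cal_bp - 3000) <= 25])
  expect_gt(spike / trough, 1.1)
})

test_that("standardization gives mean 0 / sd 1 and is affine-invariant", {
  crv <- smooth_curve()
  s <- scpd(make_dates(c(2900, 3100, 3250), c(30, 40, 50)), crv, c(2500, 3500))
  z <- standardize_scpd(s)
  expect_lt(abs(mean(z$value)), 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)

  affine <- s
  affine$value <- 3.7 * s$value + 11
  expect_equal(standardize_scpd(affine)$value, z$value, tolerance = 1e-9)

  flat <- s
  flat$value <- rep(1, nrow(s))
  expect_error(standardize_scpd(flat), "zero variance")
})

test_that("LOWESS reproduces lines exactly and attenuates spikes", {
  lin <- tibble::tibble(cal_bp = 3000:3200, value = 5 + 0.01 * (3000:3200))
  for (frac in c(0.05, 0.3, 1)) {
    sm <- lowess_smooth(lin, frac = frac)
    expect_lt(max(abs(sm$fitted - lin$value)), 1e-8)
  }

  spike <- tibble::tibble(cal_bp = 3000:3100, value = 1)
  spike$value[50] <- 10
  sm <- lowess_smooth(spike, frac = 0.3)
  expect_lt(max(sm$fitted), 10)

  expect_error(lowess_smooth(lin, frac = 0), "frac")
  expect_error(lowess_smooth(lin[1:3, ], frac = 0.5), "too few points")
})

test_that("LOWESS matches an independent tricube local-regression oracle", {
  set.seed(9)
  x <- seq(2750, 3750, by = 10)
  y <- sin((x - 2750) / 120) + rnorm(length(x), 0, 0.15)
  series <- tibble::tibble(cal_bp = x, value = y)
  for (iters in c(0, 2)) {
    sm <- lowess_smooth(series, frac = 0.25, iters = iters)
    expect_lt(max(abs(sm$fitted - oracle_lowess(x, y, 0.25, iters))), 1e-6)
  }
})

test_that("bootstrap envelope is deterministic and reduces to min/max at 2 reps", {
  crv <- smooth_curve()
  e1 <- bootstrap_envelope(crv, c(2800, 3400), n_events = 50,
                           sigma_pool = c(20, 30, 45), reps = 2, seed = 21)
  e2 <- bootstrap_envelope(crv, c(2800, 3400), n_events = 50,
                           sigma_pool = c(20, 30, 45), reps = 2, seed = 21)
  expect_equal(e1, e2)
  expect_true(all(e1$lower <= e1$upper))
  # with two reps the band is the min/max, so the mean curve sits inside
  expect_true(all(e1$fitted >= e1$lower - 1e-12 & e1$fitted <= e1$upper + 1e-12))

  expect_error(bootstrap_envelope(crv, c(2800, 3400), 0, 25, reps = 10),
               "n_events")
  expect_error(bootstrap_envelope(crv, c(2800, 3400), 10, 25, reps = 1),
               "reps")
})

test_that("envelope covers the flat null expectation on a featureless curve", {
  crv <- smooth_curve()
  w <- c(2800, 3400)
  env <- bootstrap_envelope(crv, w, n_events = 200,
                            sigma_pool = c(20, 30, 40), reps = 100, seed = 33)
  flat <- 200 / length(env$cal_bp)
  interior <- env$cal_bp >= w[1] + 60 & env$cal_bp <= w[2] - 60
  covered <- env$lower[interior] <= flat & flat <= env$upper[interior]
  expect_gte(mean(covered), 0.95)
})

test_that("logistic fit recovers noiseless parameters within 1%", {
  grid <- 2750:3750
  t <- 1950 - grid
  y <- 1 / (1 + exp(-0.01 * (t - (-1300))))
  fit <- fit_logistic(tibble::tibble(cal_bp = grid, fitted = y))
  expect_lt(abs(fit$K - 1), 0.01)
  expect_lt(abs(fit$r - 0.01) / 0.01, 0.01)
  expect_lt(abs(fit$t0 - (-1300)) / 1300, 0.01)
  expect_lt(fit$rss, 1e-10)
  td <- tidy(fit)
  expect_equal(td$term, c("K", "r", "t0"))
  expect_equal(glance(fit)$t0_cal_bp, fit$t0_cal_bp)
})

test_that("logistic fit accepts the degenerate constant-series limit", {
  grid <- 3000:3200
  fit <- fit_logistic(tibble::tibble(cal_bp = grid, fitted = rep(0.5, 201)))
  expect_lt(fit$rss, 1e-8)
  expect_lt(max(abs(fit$data$fitted - 0.5)), 1e-3)
})

test_that("logistic growth rate is recovered within 20% under 5% noise", {
  set.seed(17)
  t <- seq(-1800, -800, length.out = 1000)
  y <- 1 / (1 + exp(-0.01 * (t + 1300))) + rnorm(1000, 0, 0.05)
  fit <- fit_logistic(tibble::tibble(cal_bp = 1950 - t, fitted = y))
  expect_lt(abs(fit$r - 0.01) / 0.01, 0.2)
})

test_that("linear trend equals closed-form OLS and flags symmetric shapes", {
  grid <- 3000:3100
  lin <- tibble::tibble(cal_bp = grid, value = 2 - 0.005 * (1950 - grid))
  lt <- linear_trend(lin)
  expect_lt(max(abs(lt$residual)), 1e-10)
  expect_equal(attr(lt, "slope"), -0.005, tolerance = 1e-10)

  # symmetric parabola about the window centre: slope ~ 0
  par_y <- (grid - 3050)^2
  lt2 <- linear_trend(tibble::tibble(cal_bp = grid, value = par_y))
  expect_lt(abs(attr(lt2, "slope")), 1e-9)

  # closed-form OLS oracle on an arbitrary fixture
  set.seed(2)
  y <- rnorm(101)
  t <- 1950 - grid
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  a <- mean(y) - b * mean(t)
  lt3 <- linear_trend(tibble::tibble(cal_bp = grid, value = y))
  expect_equal(attr(lt3, "slope"), b, tolerance = 1e-10)
  expect_equal(attr(lt3, "intercept"), a, tolerance = 1e-10)
  expect_equal(lt3$trend, a + b * t, tolerance = 1e-10)
})

test_that("excursion detection finds maximal runs against a baseline", {
  grid <- 3000:3499
  base <- rep(1, 500)
  series <- tibble::tibble(cal_bp = grid, value = base)
  expect_equal(nrow(detect_excursions(series, base, min_run = 10)), 0L)

  # one 120-yr block above the baseline
  above <- series
  above$value[101:220] <- 2
  exc <- detect_excursions(above, base, min_run = 50)
  expect_equal(nrow(exc), 1L)
  expect_equal(exc$sign, "above")
  expect_equal(exc$start_cal_bp, grid[220])
  expect_equal(exc$end_cal_bp, grid[101])
  expect_equal(exc$run_years, 120)

  # min_run larger than any run -> nothing
  expect_equal(nrow(detect_excursions(above, base, min_run = 200)), 0L)

  # below + envelope reference
  env <- tibble::tibble(cal_bp = grid, lower = 0.5, upper = 1.5)
  dip <- series
  dip$value[301:360] <- 0.2
  exc2 <- detect_excursions(dip, env, min_run = 30)
  expect_equal(exc2$sign, "below")
  expect_equal(exc2$run_years, 60)
})

test_that("fitted growth direction is recovered from logistic event histories", {
  crv <- smooth_curve(2000, 5000)
  w <- c(2750, 3750)
  n_rep <- 100
  hits <- 0L
  for (i in seq_len(n_rep)) {
    r_true <- if (i %% 2 == 0) 0.008 else -0.008
    spec <- event_density_spec(
      "logistic", params = list(K = 1, r = r_true, t0_cal_bp = 3250), window = w)
    d <- simulate_dates(spec, crv, n_contexts = 500, sigma = 25, seed = 1000 + i)
    sm <- lowess_smooth(scpd(d, crv, w), frac = 0.1, iters = 2)
    fit <- tryCatch(fit_logistic(sm), error = function(e) NULL)
    if (!is.null(fit) && sign(fit$r) == sign(r_true)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
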