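# Synthetic-data generators: calibration curves with known features, date
# collections drawn from known event densities, pollen training sets and
# fossil cores with known Gaussian climate responses, metadata faults.

#' Build a synthetic calibration curve from contiguous segments
#'
#' Constructs a piecewise-linear curve mu(theta) from a table of contiguous
#' calendar segments, each with a constant slope d14C/dcal: slope 1 gives an
#' identity-like stretch, slope 0 a plateau, a steep slope a calendar-age
#' step. The curve is continuous by construction (each segment starts where
#' the previous one ends) and carries a constant 1-sigma error.
#'
#' @param segments data frame `from_bp`, `to_bp`, `slope`; segments must
#'   tile the support without gaps or overlap (ascending in cal BP).
#' @param c14_start radiocarbon age at the youngest end of the support.
#' @param error_level constant curve error (14C yr, default 20).
#' @param node_step node spacing in calendar years (default 5, the native
#'   spacing of the reference curves over this period).
#' @param name curve label.
#' @return a `cal_curve`.
#' @examples
#' # identity curve over 2000-5000 cal BP
#' crv <- make_calibration_curve(
#'   data.frame(from_bp = 2000, to_bp = 5000, slope = 1), c14_start = 2000)
#' @export
make_calibration_curve <- function(segments, c14_start, error_level = 20,
                                   node_step = 5, name = "synthetic") {
  seg <- dplyr::arrange(as_tibble(segments), .data$from_bp)
  if (!all(c("from_bp", "to_bp", "slope") %in% names(seg))) {
    abort("segments need columns from_bp, to_bp, slope.")
  }
  if (any(seg$to_bp <= seg$from_bp)) abort("each segment needs to_bp > from_bp.")
  if (nrow(seg) > 1 && any(abs(seg$from_bp[-1] - seg$to_bp[-nrow(seg)]) > 1e-9)) {
    abort("segments must tile the support contiguously (no gaps/overlaps).")
  }
  if (error_level <= 0) abort("error_level must be positive.")
  support <- c(seg$from_bp[1], seg$to_bp[nrow(seg)])
  # mu at the segment breakpoints, accumulated from the young end
  breaks <- c(seg$from_bp, support[2])
  mu_br <- c14_start + cumsum(c(0, seg$slope * (seg$to_bp - seg$from_bp)))
  nodes <- sort(unique(c(seq(support[1], support[2], by = node_step), breaks)))
  mu <- approx(breaks, mu_br, xout = nodes)$y
  calibration_curve(nodes, mu, rep(error_level, length(nodes)), name = name)
}

# Evaluate an event-density spec on a yearly grid (unnormalized).
event_density <- function(spec, grid) {
  kind <- spec$kind
  p <- spec$params
  dens <- switch(kind,
    uniform = rep(1, length(grid)),
    logistic = {
      t <- cal_forward(grid)
      p$K / (1 + exp(-p$r * (t - cal_forward(p$t0_cal_bp))))
    },
    piecewise = {
      v <- numeric(length(grid))
      for (i in seq_len(nrow(p))) {
        v[grid >= p$from_bp[i] & grid <= p$to_bp[i]] <- p$level[i]
      }
      v
    },
    mixture = {
      v <- numeric(length(grid))
      for (i in seq_len(nrow(p))) {
        v <- v + p$weight[i] * exp(-(grid - p$mean_bp[i])^2 / (2 * p$sd[i]^2))
      }
      v
    },
    abort(sprintf("unknown event density kind '%s'.", kind))
  )
  if (any(dens < 0) || all(dens == 0)) {
    abort("event density must be non-negative and not identically zero.")
  }
  dens
}

#' Event-density specification for date simulation
#'
#' Ground-truth calendar-age densities for [simulate_dates()]: `"uniform"`,
#' `"logistic"` (params `K`, `r` per yr, `t0_cal_bp`), `"piecewise"`
#' (params data frame `from_bp`, `to_bp`, `level`) or `"mixture"` of
#' Gaussians (params data frame `mean_bp`, `sd`, `weight`).
#'
#' @param kind density family.
#' @param params kind-specific parameters (see above); ignored for
#'   `"uniform"`.
#' @param window 2-vector cal BP support.
#' @return an `event_density_spec` list.
#' @export
event_density_spec <- function(kind = c("uniform", "logistic", "piecewise",
                                        "mixture"),
                               params = NULL, window) {
  kind <- match.arg(kind)
  spec <- structure(list(kind = kind, params = params,
                         window = sort(window)),
                    class = "event_density_spec")
  event_density(spec, window_grid(spec$window))  # validate now
  spec
}

#' Simulate a radiocarbon dates table from a known event density
#'
#' Draws one true calendar age per depositional context from the event
#' density (inverse-CDF on the yearly grid), then per context draws one or
#' more measurements with mean Normal(mu(age), sqrt(sigma^2 +
#' sigma_curve(age)^2)) -- the same error model calibration assumes -- and
#' the stated sigma. Site, context, class and region labels are assigned
#' round-robin. Deterministic given `seed`.
#'
#' @param density an [event_density_spec()].
#' @param curve a `cal_curve` covering the density window.
#' @param n_contexts number of depositional contexts.
#' @param dates_per_context integer (every context) or integer vector to
#'   sample from (default 1).
#' @param sigma measurement error pool (14C yr); sampled per measurement.
#' @param class_mix named proportions over context classes
#'   (default all settlement).
#' @param regions region labels, assigned round-robin.
#' @param sites_per_region sites per region, labelled `S<r>.<k>`.
#' @param seed integer seed (required for reproducibility).
#' @return a dates tibble: `lab_id`, `site_id`, `context_id`,
#'   `context_class`, `c14_age`, `sigma`, `region`, `lat`, `lon`, plus the
#'   ground-truth `true_cal_bp`.
#' @export
simulate_dates <- function(density, curve, n_contexts,
                           dates_per_context = 1L, sigma = 25,
                           class_mix = c(settlement = 1), regions = "R1",
                           sites_per_region = 5L, seed = 1L) {
  stopifnot(inherits(density, "event_density_spec"))
  set.seed(seed)
  grid <- window_grid(density$window)
  dens <- event_density(density, grid)
  true_age <- sample(grid, n_contexts, replace = TRUE, prob = dens)
  npc <- if (length(dates_per_context) == 1L) {
    rep(as.integer(dates_per_context), n_contexts)
  } else {
    sample(as.integer(dates_per_context), n_contexts, replace = TRUE)
  }
  if (any(npc < 1L)) abort("dates_per_context must be >= 1.")
  classes <- if (length(class_mix) > 1L) {
    sample(names(class_mix), n_contexts, replace = TRUE, prob = class_mix)
  } else {
    rep(names(class_mix), n_contexts)
  }
  region <- rep(regions, length.out = n_contexts)
  site <- paste0("S", match(region, regions), ".",
                 (seq_len(n_contexts) - 1L) %% sites_per_region + 1L)
  ctx <- rep(seq_len(n_contexts), npc)
  at <- curve_at(curve, true_age[ctx])
  sig <- if (length(sigma) == 1L) rep(sigma, length(ctx))
         else sample(sigma, length(ctx), replace = TRUE)
  mean_c14 <- rnorm(length(ctx), at$mu, sqrt(sig^2 + at$sigma_curve^2))
  tibble(
    lab_id = sprintf("LAB-%05d", seq_along(ctx)),
    site_id = site[ctx],
    context_id = sprintf("C%04d", ctx),
    context_class = classes[ctx],
    c14_age = mean_c14,
    sigma = sig,
    region = region[ctx],
    lat = NA_real_, lon = NA_real_,
    true_cal_bp = true_age[ctx]
  )
}

#' Gaussian taxon-response specification
#'
#' Each taxon has a Gaussian response surface over summer temperature and
#' precipitation: expected abundance proportional to
#' exp(-(t - opt_t)^2 / (2 tol_t^2)) * exp(-(p - opt_p)^2 / (2 tol_p^2)).
#'
#' @param taxa data frame `taxon`, `pft`, `opt_t`, `tol_t`, `opt_p`,
#'   `tol_p` (tolerances positive).
#' @param count_total pollen grains counted per sample.
#' @return a `response_spec` list.
#' @export
response_spec <- function(taxa, count_total = 500) {
  taxa <- as_tibble(taxa)
  need <- c("taxon", "pft", "opt_t", "tol_t", "opt_p", "tol_p")
  if (!all(need %in% names(taxa))) {
    abort(paste0("taxa table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(taxa$tol_t <= 0) || any(taxa$tol_p <= 0)) {
    abort("response tolerances must be positive.")
  }
  structure(list(taxa = taxa, count_total = count_total),
            class = "response_spec")
}

response_proportions <- function(response, t_summer, p_summer) {
  tx <- response$taxa
  m <- sapply(seq_len(nrow(tx)), function(i) {
    exp(-(t_summer - tx$opt_t[i])^2 / (2 * tx$tol_t[i]^2)) *
      exp(-(p_summer - tx$opt_p[i])^2 / (2 * tx$tol_p[i]^2))
  })
  m <- matrix(m, nrow = length(t_summer),
              dimnames = list(NULL, tx$taxon))
  m / rowSums(m)
}

# row-wise multinomial draws, robust to single-taxon communities
draw_counts <- function(props, total) {
  out <- matrix(0L, nrow(props), ncol(props),
                dimnames = list(NULL, colnames(props)))
  for (i in seq_len(nrow(props))) {
    out[i, ] <- rmultinom(1, total, props[i, ])[, 1]
  }
  out
}

# lattice placement guaranteeing a minimum pairwise great-circle distance
place_samples <- function(n, min_km, seed_lat = 40) {
  if (min_km <= 0) {
    return(tibble(lat = seq_len(n) * 0.01 + seed_lat, lon = rep(0, n)))
  }
  d_lat <- min_km / 111 * 1.05
  n_col <- max(1L, floor(sqrt(n)))
  n_row <- ceiling(n / n_col)
  max_lat <- seed_lat + (n_row - 1) * d_lat
  if (max_lat > 85) abort("min_pairwise_km spacing infeasible for n samples.")
  d_lon <- min_km / (111 * cos(max_lat * pi / 180)) * 1.05
  idx <- seq_len(n) - 1L
  tibble(lat = seed_lat + (idx %/% n_col) * d_lat,
         lon = (idx %% n_col) * d_lon)
}

#' Generate a modern pollen training set with known climate responses
#'
#' Climates are drawn uniformly within the stated ranges (or, with
#' `climate_field = "gradient"`, taken as a smooth function of the sample
#' coordinates plus noise, producing spatially autocorrelated data for
#' h-block experiments). Expected taxon proportions follow the Gaussian
#' response model; observed counts are multinomial. Coordinates are placed
#' on a lattice honouring `min_pairwise_km`.
#'
#' @param response a [response_spec()].
#' @param n_samples training-set size.
#' @param t_range,p_range climate ranges (degC JJA mean / mm JJA total).
#' @param min_pairwise_km minimum distance between any two samples (km).
#' @param climate_field `"random"` (uniform draws) or `"gradient"`
#'   (coordinate-driven, spatially autocorrelated).
#' @param seed integer seed.
#' @return list: `counts` (sample_id x taxon tibble), `metadata` (clean
#'   filter metadata), `climate` (`sample_id`, `t_summer`, `p_summer`),
#'   `mapping` (`taxon`, `pft`), `terrestrial` (taxon names).
#' @export
make_training_set <- function(response, n_samples = 300,
                              t_range = c(8, 24), p_range = c(60, 360),
                              min_pairwise_km = 0,
                              climate_field = c("random", "gradient"),
                              seed = 1L) {
  stopifnot(inherits(response, "response_spec"))
  climate_field <- match.arg(climate_field)
  if (diff(range(t_range)) <= 0 || diff(range(p_range)) <= 0) {
    abort("climate ranges must be non-degenerate.")
  }
  set.seed(seed)
  loc <- place_samples(n_samples, min_pairwise_km)
  if (climate_field == "gradient") {
    u <- (loc$lat - min(loc$lat)) / max(diff(range(loc$lat)), 1e-9)
    v <- (loc$lon - min(loc$lon)) / max(diff(range(loc$lon)), 1e-9)
    f <- (u + v) / 2
    t_summer <- t_range[1] + f * diff(t_range) +
      rnorm(n_samples, 0, diff(t_range) * 0.02)
    p_summer <- p_range[1] + (1 - f) * diff(p_range) +
      rnorm(n_samples, 0, diff(p_range) * 0.02)
  } else {
    t_summer <- runif(n_samples, t_range[1], t_range[2])
    p_summer <- runif(n_samples, p_range[1], p_range[2])
  }
  props <- response_proportions(response, t_summer, p_summer)
  counts <- draw_counts(props, response$count_total)
  ids <- sprintf("M%04d", seq_len(n_samples))
  list(
    counts = dplyr::bind_cols(tibble(sample_id = ids), as_tibble(counts)),
    metadata = tibble(sample_id = ids, lat = loc$lat, lon = loc$lon,
                      elev_recorded = 500, elev_dem = 500,
                      geoloc_error = 0, depo_context = "lake",
                      terrestrial_grains = response$count_total),
    climate = tibble(sample_id = ids, t_summer = t_summer,
                     p_summer = p_summer),
    mapping = response$taxa[, c("taxon", "pft")],
    terrestrial = response$taxa$taxon,
    seed = seed
  )
}

#' Generate a fossil pollen core with a known climate history
#'
#' Sample ages follow depth times the sedimentation rate; assemblages are
#' multinomial draws from the Gaussian response model evaluated at the
#' prescribed climate history; dated depths become age-model control points
#' whose ages carry the stated 1-sigma errors (and, with
#' `date_noise = TRUE`, Gaussian perturbations of that size). The true
#' history is returned alongside the data.
#'
#' @param climate_history function of age (cal BP) returning a list/data
#'   frame with `t_summer` and `p_summer`.
#' @param response a [response_spec()].
#' @param depths sampled depths (cm).
#' @param sed_rate sedimentation rate (yr/cm).
#' @param top_age age at depth 0 (cal BP, default 0).
#' @param dated_depths depths with dating control points (cm).
#' @param dating_errors 1-sigma errors of the control ages (yr), recycled.
#' @param date_noise perturb control ages by their stated errors.
#' @param seed integer seed.
#' @return list: `counts` (`depth` x taxon tibble), `controls`
#'   (`depth`, `age`, `age_sigma`), `truth` (`depth`, `age`, `t_summer`,
#'   `p_summer`).
#' @export
make_fossil_core <- function(climate_history, response, depths, sed_rate,
                             top_age = 0, dated_depths, dating_errors = 50,
                             date_noise = FALSE, seed = 1L) {
  stopifnot(inherits(response, "response_spec"))
  set.seed(seed)
  ages <- top_age + depths * sed_rate
  clim <- climate_history(ages)
  props <- response_proportions(response, clim$t_summer, clim$p_summer)
  counts <- draw_counts(props, response$count_total)
  err <- rep(dating_errors, length.out = length(dated_depths))
  ctl_age <- top_age + dated_depths * sed_rate
  if (date_noise) ctl_age <- ctl_age + rnorm(length(ctl_age), 0, err)
  ctl_age <- sort(ctl_age)  # keep the model monotone under noise
  list(
    counts = dplyr::bind_cols(tibble(depth = depths), as_tibble(counts)),
    controls = tibble(depth = dated_depths, age = ctl_age, age_sigma = err),
    truth = tibble(depth = depths, age = ages,
                   t_summer = clim$t_summer, p_summer = clim$p_summer),
    seed = seed
  )
}

#' Corrupt modern-sample metadata against a fault plan
#'
#' Marks disjoint samples as violating one filter rule each (geolocation
#' error above 5 km, elevation mismatch above 250 m, riverine context, or a
#' terrestrial count below 400), and returns the truth log of which rule
#' each corrupted sample violates -- the fixture for exercising
#' [filter_modern()].
#'
#' @param metadata clean metadata tibble (as from [make_training_set()]).
#' @param plan named integer vector with any of `geolocation`, `elevation`,
#'   `context`, `terrestrial_count`.
#' @param seed integer seed choosing which samples are corrupted.
#' @return list: `metadata` (corrupted), `truth` (tibble `sample_id`,
#'   `rule`).
#' @export
inject_metadata_faults <- function(metadata,
                                   plan = c(geolocation = 1, elevation = 1,
                                            context = 1,
                                            terrestrial_count = 1),
                                   seed = 1L) {
  md <- as_tibble(metadata)
  plan <- plan[plan > 0]
  bad <- setdiff(names(plan), c("geolocation", "elevation", "context",
                                "terrestrial_count"))
  if (length(bad)) abort(paste0("unknown fault rule(s): ", paste(bad, collapse = ", ")))
  if (sum(plan) > nrow(md)) abort("fault plan larger than the sample count.")
  set.seed(seed)
  victims <- sample(nrow(md), sum(plan))
  rule <- rep(names(plan), plan)
  for (i in seq_along(victims)) {
    r <- victims[i]
    switch(rule[i],
      geolocation = { md$geoloc_error[r] <- 6 },
      elevation = { md$elev_dem[r] <- md$elev_recorded[r] + 300 },
      context = { md$depo_context[r] <- "riverine" },
      terrestrial_count = { md$terrestrial_grains[r] <- 150 }
    )
  }
  list(metadata = md,
       truth = tibble(sample_id = md$sample_id[victims], rule = rule))
}
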