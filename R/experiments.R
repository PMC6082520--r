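# End-to-end recovery experiment for the regional synthesis pipeline.

#' Example Gaussian-response pollen community
#'
#' Ten taxa in five plant functional types; the two member taxa of each PFT
#' share similar optima (PFTs are ecologically coherent groups) while the
#' PFT-level optima are spread over the summer climate plane, so both
#' climate variables remain identifiable after aggregation.
#'
#' @param count_total pollen grains counted per sample.
#' @return a [response_spec()].
#' @export
example_response_spec <- function(count_total = 500) {
  response_spec(tibble(
    taxon = paste0("T", 1:10),
    pft = paste0("PFT", rep(1:5, each = 2)),
    opt_t = c(8, 9, 12, 13, 16, 17, 20, 21, 23, 24),
    tol_t = 3,
    opt_p = c(100, 115, 300, 285, 150, 165, 320, 305, 120, 135),
    tol_p = 60), count_total = count_total)
}

#' One replicate of the regional ramp-recovery experiment
#'
#' Runs the full fossil workflow against a known climate history: summer
#' temperature falls linearly by 2 degC across the 3750--2750 cal BP window
#' (from +1 to -1 around the window mean) while precipitation stays
#' constant. Three synthetic cores with noisy dated control points are
#' generated, dated with classical age-depth models, reconstructed by MAT
#' against a fresh synthetic training set, expressed as anomalies, averaged
#' into 100/50-yr windows and synthesized with the weighted regional LOESS.
#' The replicate's result is the fitted start-minus-end difference
#' (value at 3750 minus value at 2750 cal BP); the generating truth is +2.
#'
#' @param seed integer seed driving every random draw of the replicate.
#' @param n_training training-set size (default 150).
#' @return the fitted temperature difference (degC), or NA if any stage
#'   fails.
#' @export
ramp_recovery_replicate <- function(seed, n_training = 150) {
  resp <- example_response_spec()
  history <- function(age) list(t_summer = 19 + 0.002 * (age - 2750),
                                p_summer = rep(200, length(age)))
  tryCatch({
    ts <- make_training_set(resp, n_samples = n_training,
                            t_range = c(8, 24), p_range = c(60, 360),
                            seed = seed)
    props <- pft_proportions(ts$counts, ts$mapping, ts$terrestrial)
    tr <- mat_training(props, ts$climate,
                       ts$metadata[, c("sample_id", "lat", "lon")])
    depths <- seq(2, 130, by = 2)
    per_site <- list()
    samples_all <- list()
    for (i in 1:3) {
      core <- make_fossil_core(history, resp, depths = depths, sed_rate = 10,
                               top_age = 2550 + 50 * i,
                               dated_depths = c(2, 34, 66, 98, 130),
                               dating_errors = 40, date_noise = TRUE,
                               seed = seed * 10 + i)
      am <- age_model(core$controls)
      dated <- predict(am, depths)
      fossil_props <- pft_proportions(
        stats::setNames(core$counts, c("sample_id", names(core$counts)[-1])),
        ts$mapping, ts$terrestrial)
      rec <- mat_reconstruct(fossil_props, tr, k = 9)
      samples_all[[i]] <- tibble(
        site = paste0("core", i), age = dated$age,
        age_sigma = dated$age_sigma,
        t_summer = rec$t_summer, p_summer = rec$p_summer)
      per_site[[i]] <- am
    }
    pooled <- bind_rows(samples_all)
    pooled <- to_anomalies(pooled, age_col = "age", window = c(2750, 3750))
    series <- lapply(1:3, function(i) {
      s <- pooled[pooled$site == paste0("core", i), ]
      ws <- window_average(s, width = 100, step = 50, model = per_site[[i]],
                           max_dating_distance = 1000)
      ws$site_id <- paste0("core", i)
      ws
    })
    rc <- regional_loess(series, var = "t_summer", span = 0.06,
                         grid = seq(2750, 3750, by = 50))
    rc$fitted[rc$cal_bp == 3750] - rc$fitted[rc$cal_bp == 2750]
  }, error = function(e) NA_real_)
}
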