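# Modern Analogue Technique: filters, PFT aggregation, squared chord
# distance, k-analogue weighted reconstruction, cross-validation.

#' Great-circle distance in kilometres
#'
#' Haversine distance with Earth radius 6371 km, vectorized over pairs.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (WGS84).
#' @return distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 180) # half circumference, ~20015 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    abort("latitude outside [-90, 90].")
  }
  if (any(abs(c(lon1, lon2)) > 360, na.rm = TRUE)) {
    abort("longitude outside [-360, 360].")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Quality-filter modern pollen samples
#'
#' Applies the calibration-set quality rules: geolocation error no larger
#' than `geoloc_max` (strict "larger than" rejects), recorded-vs-DEM
#' elevation difference no larger than `elev_diff_max` (strict), depositional
#' context not among `excluded_contexts`, and at least `min_terrestrial`
#' terrestrial pollen grains. Missing geolocation error or DEM elevation is
#' treated as a pass (unknown, logged), so an incomplete metadata field does
#' not silently empty the training set.
#'
#' @param metadata data frame with columns `sample_id`, `geoloc_error` (km),
#'   `elev_recorded`, `elev_dem` (m), `depo_context`,
#'   `terrestrial_grains`.
#' @param geoloc_max maximum geolocation error, km (default 5).
#' @param elev_diff_max maximum |recorded - DEM| elevation, m (default 250).
#' @param min_terrestrial minimum terrestrial grain count (default 400).
#' @param excluded_contexts contexts removed because of waterborne
#'   long-distance pollen transport.
#' @return list with `samples` (retained rows) and `rejections` (tibble
#'   `sample_id`, `rule` with each sample's first failing rule) and
#'   `missing_metadata` (sample ids passed on unknown metadata).
#' @export
filter_modern <- function(metadata, geoloc_max = 5, elev_diff_max = 250,
                          min_terrestrial = 400,
                          excluded_contexts = c("riverine", "estuarine")) {
  md <- as_tibble(metadata)
  need <- c("sample_id", "geoloc_error", "elev_recorded", "elev_dem",
            "depo_context", "terrestrial_grains")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  fail_geo <- !is.na(md$geoloc_error) & md$geoloc_error > geoloc_max
  elev_diff <- abs(md$elev_recorded - md$elev_dem)
  fail_elev <- !is.na(elev_diff) & elev_diff > elev_diff_max
  fail_ctx <- md$depo_context %in% excluded_contexts
  fail_terr <- md$terrestrial_grains < min_terrestrial
  first_rule <- rep(NA_character_, nrow(md))
  first_rule[fail_terr] <- "terrestrial_count"
  first_rule[fail_ctx] <- "context"
  first_rule[fail_elev] <- "elevation"
  first_rule[fail_geo] <- "geolocation"   # rule order: geo > elev > ctx > count
  keep <- is.na(first_rule)
  list(
    samples = md[keep, , drop = FALSE],
    rejections = tibble(sample_id = md$sample_id[!keep],
                        rule = first_rule[!keep]),
    missing_metadata = md$sample_id[keep & (is.na(md$geoloc_error) |
                                              is.na(elev_diff))]
  )
}

#' Aggregate taxon counts into PFT proportions
#'
#' Converts counts to percentages over the terrestrial pollen sum, then
#' aggregates taxa into plant functional types (PFTs) and renormalizes to
#' proportions. Non-terrestrial taxa (e.g. aquatics) are excluded from the
#' sum; terrestrial taxa absent from the mapping are excluded with a
#' warning (configurable to an error).
#'
#' @param counts data frame: `sample_id` column plus one integer column per
#'   taxon.
#' @param mapping data frame `taxon`, `pft`.
#' @param terrestrial character vector of terrestrial taxon names.
#' @param unmapped "warn" (drop with a warning) or "error".
#' @return tibble: `sample_id` plus one proportion column per PFT; rows sum
#'   to 1.
#' @export
pft_proportions <- function(counts, mapping, terrestrial,
                            unmapped = c("warn", "error")) {
  unmapped <- match.arg(unmapped)
  counts <- as_tibble(counts)
  taxa <- setdiff(names(counts), "sample_id")
  terr <- intersect(taxa, terrestrial)
  if (!length(terr)) abort("no terrestrial taxa present in the counts table.")
  not_mapped <- setdiff(terr, mapping$taxon)
  if (length(not_mapped)) {
    msg <- paste0("terrestrial taxa not in PFT mapping, excluded: ",
                  paste(not_mapped, collapse = ", "))
    if (unmapped == "error") abort(msg) else warn(msg)
    terr <- setdiff(terr, not_mapped)
  }
  m <- as.matrix(counts[, terr, drop = FALSE])
  if (any(m < 0)) abort("negative pollen counts.")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("degenerate sample(s) with zero terrestrial grains: ",
                 paste(counts$sample_id[tot == 0], collapse = ", ")))
  }
  pct <- m / tot
  pfts <- sort(unique(mapping$pft[mapping$taxon %in% terr]))
  agg <- sapply(pfts, function(p) {
    members <- mapping$taxon[mapping$pft == p]
    rowSums(pct[, intersect(terr, members), drop = FALSE])
  })
  agg <- matrix(agg, nrow = nrow(pct), dimnames = list(NULL, pfts))
  agg <- agg / rowSums(agg)  # renormalize (no-op when mapping covers all)
  out <- as_tibble(agg)
  out <- dplyr::bind_cols(tibble(sample_id = counts$sample_id), out)
  out
}

#' Squared Chord Distance
#'
#' \deqn{SCD(p, q) = \sum_i (\sqrt{p_i} - \sqrt{q_i})^2}
#' between two proportion vectors on the same index. Bounded by 2; zero iff
#' the vectors are equal.
#'
#' @param p,q non-negative proportion vectors summing to 1, equal length
#'   (and equal names if named).
#' @return the distance.
#' @examples
#' scd(c(0.5, 0.5), c(1, 0)) # 0.5857864
#' @export
scd <- function(p, q) {
  if (length(p) != length(q)) abort("proportion vectors differ in length.")
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    abort("proportion vectors are on different indices.")
  }
  sum((sqrt(p) - sqrt(q))^2)
}

# SCD between every row of A and every row of B (rows = proportion vectors):
# sum((sqrt a - sqrt b)^2) = sum a + sum b - 2 sum sqrt(ab) = 2 - 2 S.
scd_matrix <- function(a, b) {
  sa <- sqrt(a); sb <- sqrt(b)
  d <- outer(rowSums(a), rowSums(b), "+") - 2 * tcrossprod(sa, sb)
  pmax(d, 0)
}

#' Assemble a MAT training set
#'
#' Bundles PFT proportion vectors with paired climate values and sample
#' locations into the object consumed by [mat_reconstruct()] and
#' [mat_cross_validate()].
#'
#' @param proportions tibble from [pft_proportions()] (or matrix with
#'   rownames as ids).
#' @param climate data frame `sample_id`, `t_summer` (degC, JJA mean),
#'   `p_summer` (mm, JJA total).
#' @param locations data frame `sample_id`, `lat`, `lon`.
#' @return a `mat_training` object.
#' @export
mat_training <- function(proportions, climate, locations) {
  if (is.data.frame(proportions)) {
    ids <- as.character(proportions$sample_id)
    m <- as.matrix(proportions[, setdiff(names(proportions), "sample_id")])
    rownames(m) <- ids
  } else {
    m <- as.matrix(proportions)
    ids <- rownames(m)
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("each assemblage proportion vector must sum to 1.")
  }
  climate <- as_tibble(climate)[match(ids, as.character(climate$sample_id)), ]
  locations <- as_tibble(locations)[match(ids, as.character(locations$sample_id)), ]
  if (any(is.na(climate$t_summer)) || any(is.na(climate$p_summer))) {
    abort("climate values missing for some training samples.")
  }
  structure(list(ids = ids, assemblages = m,
                 climate = climate[, c("t_summer", "p_summer")],
                 locations = locations[, c("lat", "lon")]),
            class = "mat_training")
}

#' @export
print.mat_training <- function(x, ...) {
  cat(sprintf("MAT training set: %d samples, %d PFTs\n",
              nrow(x$assemblages), ncol(x$assemblages)))
  invisible(x)
}

# weights for k analogue distances (ascending). Distances at or below the
# floor take all the mass (split equally): an exact analogue dominates.
analogue_weights <- function(d, scheme = c("inverse", "inverse_sq", "equal"),
                             scd_floor = 1e-6) {
  scheme <- match.arg(scheme)
  if (any(d <= scd_floor)) {
    w <- as.numeric(d <= scd_floor)
  } else {
    w <- switch(scheme, inverse = 1 / d, inverse_sq = 1 / d^2,
                equal = rep(1, length(d)))
  }
  w / sum(w)
}

#' Reconstruct climate by weighted nearest analogues
#'
#' For each target assemblage, finds the `k` training samples with the
#' smallest squared chord distance (ties broken by training order) and
#' returns the distance-weighted mean of their climate values. Weights are
#' proportional to 1/SCD with distances floored at `scd_floor`; distances
#' at the floor (exact analogues) take all the mass. With `h` and target
#' coordinates given, training samples within `h` km of the target are
#' excluded from the analogue pool (h-block exclusion).
#'
#' @param targets matrix (or `pft_proportions()` tibble) of proportion
#'   vectors on the training PFT index.
#' @param training a [mat_training()] object.
#' @param k number of analogues (default 9).
#' @param coords optional data frame `lat`, `lon` per target, required
#'   when `h` is given.
#' @param h exclusion radius in km (NULL = none).
#' @param weighting analogue weighting kernel.
#' @param scd_floor floor applied to distances before inverse weighting.
#' @return tibble with one row per target: `sample_id` (if available),
#'   `t_summer`, `p_summer`, `min_scd`, `mean_scd`, `n_pool`, and a list
#'   column `analogues` of per-target tibbles (`analogue_id`, `scd`,
#'   `weight`).
#' @export
mat_reconstruct <- function(targets, training, k = 9, coords = NULL, h = NULL,
                            weighting = "inverse", scd_floor = 1e-6) {
  stopifnot(inherits(training, "mat_training"))
  ids <- NULL
  if (is.data.frame(targets)) {
    ids <- as.character(targets$sample_id)
    targets <- as.matrix(targets[, setdiff(names(targets), "sample_id")])
  }
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  if (ncol(targets) != ncol(training$assemblages)) {
    abort("targets are not on the training PFT index.")
  }
  if (!is.null(h) && is.null(coords)) {
    abort("h-block exclusion needs target coordinates.")
  }
  d_all <- scd_matrix(targets, training$assemblages)
  n_tr <- nrow(training$assemblages)
  res <- lapply(seq_len(nrow(targets)), function(i) {
    pool <- seq_len(n_tr)
    if (!is.null(h)) {
      dist_km <- haversine_km(coords$lat[i], coords$lon[i],
                              training$locations$lat, training$locations$lon)
      pool <- pool[dist_km >= h]
    }
    if (length(pool) < k) {
      abort(sprintf("depleted analogue pool for target %d: %d candidates < k = %d.",
                    i, length(pool), k))
    }
    d <- d_all[i, pool]
    ord <- pool[order(d, pool)][seq_len(k)]  # stable tie-break by training order
    dk <- unname(d_all[i, ord])
    w <- analogue_weights(dk, weighting, scd_floor)
    tibble(
      t_summer = sum(w * training$climate$t_summer[ord]),
      p_summer = sum(w * training$climate$p_summer[ord]),
      min_scd = dk[1], mean_scd = mean(dk), n_pool = length(pool),
      analogues = list(tibble(analogue_id = training$ids[ord],
                              scd = dk, weight = w))
    )
  })
  out <- bind_rows(res)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(sample_id = ids), out)
  out
}

#' Cross-validate a MAT training set
#'
#' Predicts every training sample from the remaining pool. `"loo"` removes
#' only the sample itself; `"hblock"` additionally removes every training
#' sample within `h` km (great-circle) of the test sample, defeating
#' spatial autocorrelation. Reports, per climate variable, the squared
#' Pearson correlation of predictions vs observations (r2), the root mean
#' squared error of prediction (RMSEP) and the 1-sigma of the observed
#' values. Samples whose pool is depleted below `k` are flagged, excluded
#' from the summary, and a warning is raised.
#'
#' @param training a [mat_training()] object.
#' @param mode `"loo"` or `"hblock"`.
#' @param h exclusion radius in km for h-block (default 100).
#' @param k analogues per prediction (default 9).
#' @param weighting,scd_floor passed to [mat_reconstruct()].
#' @return a `mat_cv` object; `tidy()` gives per-variable r2/RMSEP/sd,
#'   `glance()` a one-row summary, `$per_sample` the prediction table.
#' @export
mat_cross_validate <- function(training, mode = c("loo", "hblock"), h = 100,
                               k = 9, weighting = "inverse",
                               scd_floor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(training, "mat_training"))
  n <- nrow(training$assemblages)
  d_all <- scd_matrix(training$assemblages, training$assemblages)
  lat <- training$locations$lat; lon <- training$locations$lon
  rows <- lapply(seq_len(n), function(i) {
    pool <- setdiff(seq_len(n), i)
    if (mode == "hblock") {
      dist_km <- haversine_km(lat[i], lon[i], lat[pool], lon[pool])
      pool <- pool[dist_km >= h]
    }
    if (length(pool) < k) {
      return(tibble(sample_id = training$ids[i],
                    t_obs = training$climate$t_summer[i],
                    p_obs = training$climate$p_summer[i],
                    t_pred = NA_real_, p_pred = NA_real_,
                    min_analogue_km = NA_real_, depleted = TRUE))
    }
    d <- d_all[i, pool]
    ord <- pool[order(d, pool)][seq_len(k)]
    w <- analogue_weights(d_all[i, ord], weighting, scd_floor)
    tibble(sample_id = training$ids[i],
           t_obs = training$climate$t_summer[i],
           p_obs = training$climate$p_summer[i],
           t_pred = sum(w * training$climate$t_summer[ord]),
           p_pred = sum(w * training$climate$p_summer[ord]),
           min_analogue_km = min(haversine_km(lat[i], lon[i], lat[ord], lon[ord])),
           depleted = FALSE)
  })
  per_sample <- bind_rows(rows)
  if (any(per_sample$depleted)) {
    warn(sprintf("%d sample(s) had depleted analogue pools and were excluded from the summary.",
                 sum(per_sample$depleted)))
  }
  ok <- !per_sample$depleted
  stat <- function(obs, pred) {
    if (sum(ok) < 2L) return(c(r2 = NA_real_, rmsep = NA_real_, sd = sd(obs)))
    c(r2 = suppressWarnings(stats::cor(obs[ok], pred[ok]))^2,
      rmsep = sqrt(mean((pred[ok] - obs[ok])^2)),
      sd = sd(obs))
  }
  st <- stat(per_sample$t_obs, per_sample$t_pred)
  sp <- stat(per_sample$p_obs, per_sample$p_pred)
  structure(list(
    mode = mode, h = if (mode == "hblock") h else NA_real_, k = k,
    summary = tibble(
      variable = c("t_summer", "p_summer"),
      r2 = c(st["r2"], sp["r2"]),
      rmsep = c(st["rmsep"], sp["rmsep"]),
      sd_observed = c(st["sd"], sp["sd"]),
      n = sum(ok)),
    per_sample = per_sample
  ), class = "mat_cv")
}

#' @export
print.mat_cv <- function(x, ...) {
  cat(sprintf("MAT %s cross-validation (k = %d%s)\n", x$mode, x$k,
              if (!is.na(x$h)) sprintf(", h = %g km", x$h) else ""))
  print(x$summary)
  invisible(x)
}

#' Tidy a MAT cross-validation report
#' @param x a `mat_cv`.
#' @param ... unused.
#' @return per-variable tibble `variable`, `r2`, `rmsep`, `sd_observed`, `n`.
#' @method tidy mat_cv
#' @export
tidy.mat_cv <- function(x, ...) x$summary

#' @rdname tidy.mat_cv
#' @method glance mat_cv
#' @export
glance.mat_cv <- function(x, ...) {
  s <- x$summary
  tibble(mode = x$mode, h = x$h, k = x$k,
         r2_t = s$r2[s$variable == "t_summer"],
         rmsep_t = s$rmsep[s$variable == "t_summer"],
         sd_t = s$sd_observed[s$variable == "t_summer"],
         r2_p = s$r2[s$variable == "p_summer"],
         rmsep_p = s$rmsep[s$variable == "p_summer"],
         sd_p = s$sd_observed[s$variable == "p_summer"],
         n = s$n[1])
}

#' Regular climate raster and nearest-pixel lookup
#'
#' A minimal regular lat/lon raster of climate pairs, mimicking
#' nearest-pixel extraction from gridded climatology maps. `xll`/`yll` are
#' the lower-left corner of the extent (pixel edges); pixel centres sit at
#' `ll + (index - 0.5) * cellsize`. Matrices are indexed `[row, col]` with
#' row 1 the southernmost row.
#'
#' @param xll,yll lower-left corner (degrees lon / lat).
#' @param cellsize pixel size in degrees.
#' @param t_summer,p_summer value matrices (nrow = rows northward).
#' @return a `climate_grid` object.
#' @export
climate_grid <- function(xll, yll, cellsize, t_summer, p_summer) {
  stopifnot(is.matrix(t_summer), identical(dim(t_summer), dim(p_summer)))
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 t_summer = t_summer, p_summer = p_summer),
            class = "climate_grid")
}

#' @rdname climate_grid
#' @param grid a `climate_grid`.
#' @param lat,lon query coordinates (decimal degrees), vectorized.
#' @return `grid_lookup`: tibble `t_summer`, `p_summer` of the pixel
#'   containing (= nearest centre to) each point.
#' @export
grid_lookup <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "climate_grid"))
  nr <- nrow(grid$t_summer); nc <- ncol(grid$t_summer)
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row <- floor((lat - grid$yll) / grid$cellsize) + 1
  # points on the far edges belong to the last pixel
  col[lon == grid$xll + nc * grid$cellsize] <- nc
  row[lat == grid$yll + nr * grid$cellsize] <- nr
  if (any(col < 1 | col > nc | row < 1 | row > nr)) {
    abort("point outside the raster extent.")
  }
  tibble(t_summer = grid$t_summer[cbind(row, col)],
         p_summer = grid$p_summer[cbind(row, col)])
}
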