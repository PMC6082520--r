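# Readers and writers for the package's plain-text dialects, and the run
# configuration object.

dates_columns <- c("lab_id", "site_id", "context_id", "context_class",
                   "c14_age", "sigma", "region", "lat", "lon")

#' Read a radiocarbon dates table
#'
#' CSV dialect: header
#' `lab_id,site_id,context_id,context_class,c14_age,sigma,region,lat,lon`;
#' missing lat/lon allowed. `col_map` renames deposit-specific headers to
#' this dialect (names = file columns, values = canonical names). Rows with
#' non-numeric or non-positive `c14_age`/`sigma` are skipped with a warning
#' naming the data line.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping file columns to
#'   canonical names.
#' @return a dates tibble.
#' @export
read_dates_table <- function(path, col_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    names(df)[idx[!is.na(idx)]] <- unname(col_map[!is.na(idx)])
  }
  mandatory <- c("lab_id", "site_id", "context_id", "context_class",
                 "c14_age", "sigma")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    abort(paste0("dates file lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in setdiff(dates_columns, names(df))) df[[col]] <- NA_character_
  c14 <- suppressWarnings(as.numeric(df$c14_age))
  sig <- suppressWarnings(as.numeric(df$sigma))
  bad <- !is.finite(c14) | !is.finite(sig) | sig <= 0
  if (any(bad)) {
    warn(paste0("skipped ", sum(bad), " malformed date row(s) at data line(s): ",
                paste(which(bad), collapse = ", ")))
  }
  out <- df[!bad, dates_columns]
  out$c14_age <- c14[!bad]
  out$sigma <- sig[!bad]
  out$lat <- suppressWarnings(as.numeric(out$lat))
  out$lon <- suppressWarnings(as.numeric(out$lon))
  out
}

#' @rdname read_dates_table
#' @param dates dates tibble to write.
#' @export
write_dates_table <- function(dates, path) {
  readr::write_csv(dates[, intersect(dates_columns, names(dates))], path)
  invisible(path)
}

#' Read/write SCPD and smoothed series
#'
#' CSV layout `cal_bp,value[,lower,upper]` (smoothed series store their
#' fitted values in `value`).
#'
#' @param series an `scpd_series`, `smoothed_series` or compatible tibble.
#' @param path CSV path.
#' @return `read_series`: a tibble; `write_series`: the path, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as_tibble(series)
  if ("fitted" %in% names(df)) names(df)[names(df) == "fitted"] <- "value"
  keep <- intersect(c("cal_bp", "value", "lower", "upper"), names(df))
  readr::write_csv(df[, keep], path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run configuration with the study defaults
#'
#' Bundles every tunable threshold of the two workflows with its default:
#' the radiocarbon screening cutoff (`sigma_max` = 95 yr), the same-event
#' test level (`alpha` = 0.05), the analysis window (1800--800 BC, i.e.
#' 3750--2750 cal BP), LOWESS span/iterations, bootstrap replicates (500),
#' analogue count (`k` = 9), h-block radius (`h` = 100 km), regional LOESS
#' span (0.06), window width/step (100/50 yr), dating-distance mask
#' (1000 yr) and the modern-sample filter thresholds (5 km, 250 m, 400
#' grains).
#'
#' @param ... overrides of the defaults by name.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    sigma_max = 95, alpha = 0.05,
    window = c(bc_to_bp(800), bc_to_bp(1800)),
    lowess_frac = 0.1, lowess_iters = 2,
    envelope_reps = 500, k = 9, h = 100, span = 0.06,
    window_width = 100, window_step = 50, mask_distance = 1000,
    geoloc_max = 5, elev_diff_max = 250, min_terrestrial = 400,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  thresholds <- c("sigma_max", "alpha", "lowess_frac", "envelope_reps", "k",
                  "h", "span", "window_width", "window_step", "mask_distance",
                  "geoloc_max", "elev_diff_max", "min_terrestrial")
  if (any(unlist(cfg[thresholds]) <= 0)) abort("all thresholds must be positive.")
  if (diff(range(cfg$window)) <= 0) abort("window must be non-empty.")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
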