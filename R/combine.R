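# Same-event testing and combination of radiocarbon measurements.

check_dates_df <- function(dates, need = c("c14_age", "sigma")) {
  missing <- setdiff(need, names(dates))
  if (length(missing)) {
    abort(paste0("dates table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(dates$c14_age))) abort("c14_age must be finite.")
  if (any(dates$sigma <= 0)) abort("sigma must be positive.")
  invisible(dates)
}

#' Inverse-variance pooled mean of same-event measurements
#'
#' Pools several radiocarbon determinations of the same depositional event
#' into a single measurement:
#' \deqn{\bar x = \sum (x_i/\sigma_i^2) / \sum (1/\sigma_i^2), \quad
#'   \bar\sigma = (\sum 1/\sigma_i^2)^{-1/2}.}
#' Metadata (lab and site identifiers, class, region, coordinates) is taken
#' from the first row; the context identifier is preserved.
#'
#' @param dates data frame of measurements with columns `c14_age`, `sigma`
#'   and optional metadata columns; at least one row.
#' @return a one-row tibble in the same layout with pooled `c14_age`,
#'   `sigma` and an `n_pooled` column.
#' @examples
#' pooled_mean(data.frame(c14_age = c(3000, 3100), sigma = c(20, 40)))
#' @export
pooled_mean <- function(dates) {
  dates <- as_tibble(dates)
  if (nrow(dates) == 0L) abort("pooled_mean needs at least one measurement.")
  check_dates_df(dates)
  w <- 1 / dates$sigma^2
  out <- dates[1, , drop = FALSE]
  out$c14_age <- sum(w * dates$c14_age) / sum(w)
  out$sigma <- 1 / sqrt(sum(w))
  out$n_pooled <- nrow(dates)
  out
}

#' Ward--Wilson chi-square test for same-age measurements
#'
#' Tests whether a group of radiocarbon determinations is consistent with a
#' single true age. The statistic is
#' \deqn{T = \sum_i (x_i - \bar x)^2 / \sigma_i^2}
#' with \eqn{\bar x} the inverse-variance pooled mean; under the null it is
#' chi-square with \eqn{n - 1} degrees of freedom. The group passes (may be
#' combined) when the upper-tail p-value is at least `alpha`.
#'
#' @param dates data frame with columns `c14_age`, `sigma`; at least 2 rows.
#' @param alpha significance level gating combination (default 0.05).
#' @return one-row tibble: `statistic`, `dof`, `p_value`, `passed`.
#' @examples
#' ward_wilson(data.frame(c14_age = c(3000, 3200), sigma = c(30, 30)))
#' @export
ward_wilson <- function(dates, alpha = 0.05) {
  dates <- as_tibble(dates)
  if (nrow(dates) < 2L) abort("ward_wilson needs at least two measurements.")
  check_dates_df(dates)
  w <- 1 / dates$sigma^2
  xbar <- sum(w * dates$c14_age) / sum(w)
  statistic <- sum((dates$c14_age - xbar)^2 / dates$sigma^2)
  dof <- nrow(dates) - 1L
  p <- pchisq(statistic, df = dof, lower.tail = FALSE)
  tibble(statistic = statistic, dof = dof, p_value = p, passed = p >= alpha)
}

#' Combine same-context radiocarbon dates into depositional events
#'
#' Groups a dates table by `(site_id, context_id)`. Singleton contexts pass
#' through untouched. Multi-date contexts are tested with [ward_wilson()]:
#' groups that pass are replaced by their [pooled_mean()]; groups that fail
#' are retained as separate rows and flagged, so no data is silently dropped
#' and the number of represented `(site, context)` events never changes.
#'
#' @param dates data frame with columns `site_id`, `context_id`, `c14_age`,
#'   `sigma` plus metadata.
#' @param alpha significance level for the Ward--Wilson gate.
#' @return tibble of event-level rows with added columns `n_dates`,
#'   `combined`, `statistic`, `p_value`, `passed` (NA for singletons) and
#'   `flagged` (TRUE where a group failed the test and members were kept).
#' @export
combine_contexts <- function(dates, alpha = 0.05) {
  dates <- as_tibble(dates)
  check_dates_df(dates, c("site_id", "context_id", "c14_age", "sigma"))
  key <- paste(dates$site_id, dates$context_id, sep = "\r")
  groups <- split(seq_len(nrow(dates)), key)
  # keep first-appearance order of contexts
  groups <- groups[order(vapply(groups, min, 1L))]
  pieces <- lapply(groups, function(idx) {
    g <- dates[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      g$n_dates <- 1L
      g$combined <- FALSE
      g$statistic <- NA_real_
      g$p_value <- NA_real_
      g$passed <- NA
      g$flagged <- FALSE
      return(g)
    }
    ww <- ward_wilson(g, alpha = alpha)
    if (ww$passed) {
      out <- pooled_mean(g)
      out$n_pooled <- NULL
      out$n_dates <- length(idx)
      out$combined <- TRUE
      out$statistic <- ww$statistic
      out$p_value <- ww$p_value
      out$passed <- TRUE
      out$flagged <- FALSE
      out
    } else {
      g$n_dates <- length(idx)
      g$combined <- FALSE
      g$statistic <- ww$statistic
      g$p_value <- ww$p_value
      g$passed <- FALSE
      g$flagged <- TRUE
      g
    }
  })
  bind_rows(pieces)
}
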