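#' Configuration for the resting-heart-rate search
#'
#' The estimator scans step thresholds `n` (maximum rolling step sum
#' tolerated inside a lookback window) crossed with window lengths `m`
#' (minutes), scoring each candidate low-activity heart-rate subset with a
#' standard-deviation penalty.
#'
#' @param n_grid step-count thresholds (default 0..10 then 15,20,...,50).
#' @param m_grid lookback window lengths in minutes (default 5,10,...,60).
#' @param lambda weight of the coverage-shortfall penalty term (>= 0).
#' @param min_fraction minimum subset size as a fraction of all heart-rate
#'   samples before the shortfall penalty saturates (in (0, 1]).
#' @param min_days minimum number of distinct calendar days the subset must
#'   touch; `NULL` (default) resolves to `min(3, observed span in days)`.
#' @return An object of class `rhr_config`.
#' @export
rhr_config <- function(n_grid = c(0:10, seq(15, 50, by = 5)),
                       m_grid = seq(5, 60, by = 5),
                       lambda = 1.0, min_fraction = 0.10, min_days = NULL) {
  if (length(n_grid) == 0 || is.unsorted(n_grid, strictly = TRUE))
    wb_contract_error("n_grid must be non-empty and strictly increasing")
  if (length(m_grid) == 0 || is.unsorted(m_grid, strictly = TRUE) ||
      any(m_grid < 1))
    wb_contract_error("m_grid must be non-empty, strictly increasing, >= 1")
  if (lambda < 0) wb_contract_error("lambda must be >= 0")
  if (min_fraction <= 0 || min_fraction > 1)
    wb_contract_error("min_fraction must be in (0, 1]")
  structure(list(n_grid = n_grid, m_grid = m_grid, lambda = lambda,
                 min_fraction = min_fraction, min_days = min_days),
            class = "rhr_config")
}

#' Trailing rolling sum of step counts
#'
#' Value at time t is the sum of step counts over the half-open lookback
#' window (t - m minutes, t]; on a 1-minute grid this is the current sample
#' plus the previous m - 1. The first m - 1 minutes use the partial window.
#'
#' @param steps a [bio_series] of channel `steps` on a 1-minute grid
#'   (zero-filled, see [resample_uniform]).
#' @param m window length in minutes (>= 1).
#' @return A [bio_series] of rolling sums on the same grid.
#' @export
rolling_step_sum <- function(steps, m) {
  if (length(steps) == 0) wb_empty_input("steps series is empty")
  if (m < 1) wb_contract_error("m must be >= 1")
  v <- steps$value
  cs <- cumsum(v)
  lag <- c(rep(0, min(m, length(v))), cs[seq_len(max(0, length(v) - m))])
  bio_series(steps$time, cs - lag, "steps", steps$nominal_interval,
             steps$subject_id)
}

#' Heart-rate samples during low step activity
#'
#' @param hr,steps [bio_series] objects already aligned to a common
#'   1-minute grid (see [align_series]); only timestamps present in both
#'   are considered.
#' @param n maximum rolling step sum tolerated.
#' @param m lookback window in minutes.
#' @return A [bio_series] of the heart-rate samples at times whose rolling
#'   step sum is `<= n`, in time order.
#' @export
low_activity_subset <- function(hr, steps, n, m) {
  rs <- rolling_step_sum(steps, m)
  keep_t <- as.numeric(rs$time)[rs$value <= n]
  idx <- which(as.numeric(hr$time) %in% keep_t)
  if (length(intersect(as.numeric(hr$time), as.numeric(steps$time))) == 0)
    wb_empty_input("heart-rate and step series do not overlap")
  series_subset(hr, idx)
}

# SD with the n-1 denominator, defined as 0 for a single value.
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Standard-deviation penalty of a candidate resting subset
#'
#' \eqn{P = SD(subset) + \lambda\, SD(full) \cdot
#'  \max(0,\; f N - |subset|) / (f N)} with `f = min_fraction` and `N` the
#' full heart-rate sample count. An empty subset, or one touching fewer
#' distinct days than `min_days`, is disqualified with `P = +Inf`.
#' Minimizing subset SD alone collapses onto near-empty subsets; the
#' shortfall term keeps the optimum a low-variation subset that still
#' represents the data.
#'
#' @param hr_full the full heart-rate [bio_series].
#' @param subset the candidate low-activity subset (a [bio_series]).
#' @param config an [rhr_config].
#' @return The penalty value (may be `Inf`).
#' @export
rhr_penalty <- function(hr_full, subset, config = rhr_config()) {
  if (length(hr_full) == 0) wb_empty_input("hr_full is empty")
  min_days <- resolve_min_days(config, hr_full)
  penalty_core(hr_full$value, subset$value,
               n_days_subset = length(unique(series_dates(subset))),
               min_days = min_days, config = config)
}

penalty_core <- function(full_values, subset_values, n_days_subset,
                         min_days, config) {
  if (length(subset_values) == 0 || n_days_subset < min_days) return(Inf)
  N <- length(full_values)
  target <- config$min_fraction * N
  shortfall <- max(0, target - length(subset_values)) / target
  sd0(subset_values) + config$lambda * sd0(full_values) * shortfall
}

resolve_min_days <- function(config, hr) {
  if (!is.null(config$min_days)) return(config$min_days)
  min(3, length(unique(series_dates(hr))))
}

#' Estimate resting heart rate by penalized low-activity subset search
#'
#' Exhaustive grid search over `n_grid x m_grid`: for each pair the
#' heart-rate subset at times whose trailing `m`-minute step sum is `<= n`
#' is scored with [rhr_penalty]; the minimizer (ties broken by smaller `m`,
#' then smaller `n`) defines the optimal subset, and the resting heart rate
#' is its median (even sizes: mean of the central pair).
#'
#' @param hr heart-rate [bio_series]; resampled to a 1-minute grid if
#'   coarser/finer, with a warning.
#' @param steps step-count [bio_series]; resampled (sum, zero-filled) to
#'   the same grid.
#' @param config an [rhr_config].
#' @return An object of class `rhr_estimate`: `rhr`, `n_star`, `m_star`,
#'   `subset_size`, `penalty_value`, `per_day_medians`, `search_table`
#'   (data frame `n`, `m`, `subset_size`, `subset_sd`, `penalty`),
#'   `n_total`, `min_days`.
#' @export
search_rhr <- function(hr, steps, config = rhr_config()) {
  if (length(hr) == 0 || length(steps) == 0)
    wb_empty_input("hr and steps must be non-empty")
  if (hr$nominal_interval != 60 || steps$nominal_interval != 60)
    warning("resampling inputs to a shared 1-minute grid", call. = FALSE)
  hr_g <- resample_uniform(hr, 60, "mean")
  st_g <- resample_uniform(steps, 60, "sum")
  common <- intersect(as.numeric(hr_g$time), as.numeric(st_g$time))
  if (length(common) == 0) wb_empty_input("hr and steps do not overlap in time")
  hr_v  <- hr_g$value[match(common, as.numeric(hr_g$time))]
  hr_t  <- sort(common)
  ord   <- order(common)
  hr_v  <- hr_v[ord]
  dates <- as.Date(as.POSIXct(hr_t, origin = "1970-01-01",
                              tz = series_tz(hr)), tz = series_tz(hr))
  date_id <- as.integer(factor(dates))
  min_days <- if (!is.null(config$min_days)) config$min_days else
    min(3, max(date_id))
  span_days <- as.numeric(max(hr_t) - min(hr_t)) / 86400
  if (span_days < 1)
    warning("less than one full day of overlapping data", call. = FALSE)

  # Rolling sums are computed once per m on the full zero-filled step grid,
  # then restricted to the heart-rate timestamps.
  st_idx <- match(hr_t, as.numeric(st_g$time))
  rows <- vector("list", length(config$m_grid) * length(config$n_grid))
  r <- 0L
  for (m in config$m_grid) {
    rs <- rolling_step_sum(st_g, m)$value[st_idx]
    for (n in config$n_grid) {
      keep <- rs <= n
      sv <- hr_v[keep]
      p <- penalty_core(hr_v, sv, n_days_subset = length(unique(date_id[keep])),
                        min_days = min_days, config = config)
      r <- r + 1L
      rows[[r]] <- c(n, m, length(sv), if (length(sv)) sd0(sv) else NA_real_, p)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("n", "m", "subset_size", "subset_sd", "penalty")
  if (all(!is.finite(tab$penalty)))
    wb_no_resting_data(sprintf(
      "no (n, m) candidate qualifies: every subset is empty or touches fewer than %d distinct day(s)",
      min_days))
  best <- order(tab$penalty, tab$m, tab$n)[1]
  n_star <- tab$n[best]; m_star <- tab$m[best]
  rs <- rolling_step_sum(st_g, m_star)$value[st_idx]
  keep <- rs <= n_star
  subset_v <- hr_v[keep]
  per_day <- tapply(subset_v, dates[keep], stats::median)
  structure(list(
    rhr = stats::median(subset_v),
    n_star = n_star, m_star = m_star,
    subset_size = length(subset_v),
    penalty_value = tab$penalty[best],
    per_day_medians = per_day,
    search_table = tab,
    n_total = length(hr_v),
    min_days = min_days
  ), class = "rhr_estimate")
}

#' @export
#' @method print rhr_estimate
print.rhr_estimate <- function(x, ...) {
  cat(sprintf("Resting heart rate: %.1f bpm\n", x$rhr))
  cat(sprintf("  optimal (n, m): steps <= %g in a %g-minute window\n",
              x$n_star, x$m_star))
  cat(sprintf("  subset: %d of %d minutes (%.1f%%), penalty %.3f\n",
              x$subset_size, x$n_total, 100 * x$subset_size / x$n_total,
              x$penalty_value))
  invisible(x)
}

#' @export
#' @method summary rhr_estimate
summary.rhr_estimate <- function(object, ...) {
  cat(sprintf("Resting heart rate estimate: %.1f bpm (n* = %g, m* = %g)\n\n",
              object$rhr, object$n_star, object$m_star))
  cat("Per-day medians of the optimal subset (bpm):\n")
  print(round(object$per_day_medians, 1))
  finite <- object$search_table[is.finite(object$search_table$penalty), ]
  cat(sprintf("\nSearch: %d candidates, %d qualifying; penalty range [%.3f, %.3f]\n",
              nrow(object$search_table), nrow(finite),
              min(finite$penalty), max(finite$penalty)))
  invisible(object)
}

#' @export
plot.rhr_estimate <- function(x, ...) {
  tab <- x$search_table
  m_vals <- sort(unique(tab$m)); n_vals <- sort(unique(tab$n))
  z <- matrix(tab$penalty[order(tab$m, tab$n)], nrow = length(n_vals))
  z[!is.finite(z)] <- NA
  graphics::image(x = seq_along(n_vals), y = seq_along(m_vals), z = z,
                  xlab = "step threshold n", ylab = "window m (min)",
                  axes = FALSE,
                  col = grDevices::hcl.colors(32, "viridis"), ...)
  graphics::axis(1, at = seq_along(n_vals), labels = n_vals)
  graphics::axis(2, at = seq_along(m_vals), labels = m_vals, las = 1)
  graphics::points(match(x$n_star, n_vals), match(x$m_star, m_vals),
                   pch = 4, cex = 2, lwd = 2)
  graphics::box()
  invisible(x)
}

#' Resting heart rate from CSV files (read, validate, resample, search)
#'
#' @param hr_path,steps_path long-format CSV paths (see [read_series]).
#' @param config an [rhr_config].
#' @param timezone timezone for timestamp parsing.
#' @param out_json optional path: write the estimate as a JSON report.
#' @return An `rhr_estimate` (see [search_rhr]).
#' @export
estimate_rhr <- function(hr_path, steps_path, config = rhr_config(),
                         timezone = "UTC", out_json = NULL) {
  hr <- with_stage("read", read_series(hr_path, "heart_rate",
                                       timezone = timezone))
  st <- with_stage("read", read_series(steps_path, "steps",
                                       timezone = timezone))
  hr <- with_stage("validate", validate_series(hr))$series
  st <- with_stage("validate", validate_series(st))$series
  est <- with_stage("search", search_rhr(hr, st, config))
  if (!is.null(out_json)) {
    rep <- list(rhr = est$rhr, n_star = est$n_star, m_star = est$m_star,
                subset_size = est$subset_size,
                penalty_value = est$penalty_value,
                per_day_medians = as.list(est$per_day_medians))
    atomic_write_json(rep, out_json)
  }
  est
}

# Atomic write: temp file in the target directory, then rename.
atomic_write_json <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
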