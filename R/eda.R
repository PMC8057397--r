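#' Per-day and per-hour data completeness
#'
#' Quantifies the fraction of wearable data present, the basis for
#' day-by-hour completeness heat grids. Presence is counted per nominal
#' grid slot (a sample anywhere inside the slot marks it present), so
#' oversampling cannot exceed 100%. Per-day fractions always use the full
#' 24-hour day as denominator so days are comparable; hours outside the
#' observed span of partial first/last days count as 0.
#'
#' @param series a non-empty [bio_series].
#' @param nominal_interval expected sampling interval in seconds; must
#'   divide 3600. Defaults to the series' own nominal interval.
#' @return An object of class `missingness_summary`: list with
#'   `per_day_hour` (data frame `date`, `hour`, `fraction` covering every
#'   hour of every calendar day in the observed range), `per_day`
#'   (data frame `date`, `fraction`), `expected_per_hour`,
#'   `expected_per_day`.
#' @export
missingness_by_day_hour <- function(series,
                                    nominal_interval = series$nominal_interval) {
  if (length(series) == 0) wb_empty_input("series is empty")
  if (nominal_interval <= 0 || 3600 %% nominal_interval != 0)
    wb_contract_error("nominal_interval must be positive and divide 3600")
  expected_per_hour <- 3600 / nominal_interval
  tz <- series_tz(series)
  slots <- unique(floor(series_epoch(series) / nominal_interval) *
                    nominal_interval)
  slot_t <- as.POSIXct(slots, origin = "1970-01-01", tz = tz)
  slot_date <- as.Date(slot_t, tz = tz)
  slot_hour <- as.integer(format(slot_t, "%H", tz = tz))
  counts <- stats::aggregate(
    list(n = slots),
    by = list(date = slot_date, hour = slot_hour),
    FUN = length)
  days <- seq(min(slot_date), max(slot_date), by = "day")
  grid <- expand.grid(hour = 0:23, date = days)[, c("date", "hour")]
  m <- merge(grid, counts, by = c("date", "hour"), all.x = TRUE)
  m$n[is.na(m$n)] <- 0L
  m$fraction <- m$n / expected_per_hour
  m <- m[order(m$date, m$hour), c("date", "hour", "fraction")]
  rownames(m) <- NULL
  per_day <- stats::aggregate(list(fraction = m$fraction),
                              by = list(date = m$date), FUN = mean)
  structure(
    list(per_day_hour = m, per_day = per_day,
         expected_per_hour = as.integer(expected_per_hour),
         expected_per_day = as.integer(24 * expected_per_hour)),
    class = "missingness_summary"
  )
}

#' @export
#' @method print missingness_summary
print.missingness_summary <- function(x, ...) {
  cat(sprintf("<missingness_summary> %d day(s), expecting %d samples/hour\n",
              nrow(x$per_day), x$expected_per_hour))
  print(x$per_day, row.names = FALSE)
  invisible(x)
}

#' Heat-grid of data presence (day x hour)
#'
#' @param x a `missingness_summary`.
#' @param ... passed to [graphics::image].
#' @export
plot.missingness_summary <- function(x, ...) {
  days <- sort(unique(x$per_day_hour$date))
  z <- matrix(x$per_day_hour$fraction, nrow = 24,
              dimnames = list(0:23, format(days)))
  graphics::image(x = 0:23, y = seq_along(days), z = z[, , drop = FALSE],
                  xlab = "hour of day", ylab = "day", axes = FALSE,
                  zlim = c(0, 1),
                  col = grDevices::hcl.colors(32, "YlGnBu", rev = TRUE), ...)
  graphics::axis(1, at = seq(0, 23, 3))
  graphics::axis(2, at = seq_along(days), labels = format(days, "%m-%d"),
                 las = 1)
  graphics::box()
  invisible(x)
}

#' Flag implausible and spiking samples
#'
#' Two rules: (i) value outside the channel's plausibility bounds;
#' (ii) absolute deviation from the rolling median (15-minute window)
#' exceeding `spike_sd` times the rolling robust SD (1.4826 x MAD). If the
#' series is shorter than the rolling window only the bounds rule runs,
#' with a warning.
#'
#' @param series a [bio_series].
#' @param bounds a [plausibility_bounds].
#' @param spike_sd spike threshold in robust SDs (default 5).
#' @param window_s rolling window length in seconds (default 900 = 15 min).
#' @return An `outlier_report`: list with `indices`, `rule` (one string per
#'   flagged index), `flagged_count`.
#' @export
flag_outliers <- function(series, bounds = plausibility_bounds(series$channel),
                          spike_sd = 5, window_s = 900) {
  if (!is.numeric(spike_sd) || spike_sd <= 0)
    wb_contract_error("spike_sd must be positive")
  v <- series$value
  flag_bounds <- which(v < bounds$low | v > bounds$high)
  k <- floor(window_s / series$nominal_interval)
  if (k %% 2 == 0) k <- k + 1
  flag_spike <- integer(0)
  if (length(v) < k) {
    warning("series shorter than rolling window; bounds rule only",
            call. = FALSE)
  } else {
    rmed <- stats::runmed(v, k, endrule = "median")
    half <- (k - 1) / 2
    rsd <- vapply(seq_along(v), function(i) {
      w <- v[max(1, i - half):min(length(v), i + half)]
      stats::mad(w)  # 1.4826 x MAD
    }, numeric(1))
    dev <- abs(v - rmed)
    flag_spike <- which(dev > spike_sd * rsd & dev > 0)
  }
  idx <- sort(union(flag_bounds, flag_spike))
  rule <- vapply(idx, function(i) {
    paste(c(if (i %in% flag_bounds) "bounds",
            if (i %in% flag_spike) "spike"), collapse = "+")
  }, character(1))
  structure(list(indices = idx, rule = rule, flagged_count = length(idx)),
            class = "outlier_report")
}

#' @export
#' @method print outlier_report
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d sample(s) flagged\n", x$flagged_count))
  if (x$flagged_count)
    print(data.frame(index = x$indices, rule = x$rule), row.names = FALSE)
  invisible(x)
}

#' Standard descriptive summary of a series
#'
#' @param series a non-empty [bio_series].
#' @return A named list: `n`, `mean`, `sd` (n-1 denominator; 0 with a
#'   warning for a single sample), `min`, `q1`, `median`, `q3`, `max`,
#'   `span_days`.
#' @export
summarize_series <- function(series) {
  if (length(series) == 0) wb_empty_input("series is empty")
  v <- series$value
  s <- if (length(v) < 2) {
    warning("single sample: sd reported as 0", call. = FALSE)
    0
  } else stats::sd(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(v), mean = mean(v), sd = s, min = min(v),
       q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       span_days = as.numeric(difftime(series$time[length(v)],
                                       series$time[1], units = "days")))
}
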