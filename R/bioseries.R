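# Channel registry: units and default resampling aggregator.
.wb_channels <- data.frame(
  channel    = c("heart_rate", "steps", "glucose"),
  units      = c("bpm", "count/interval", "mg/dL"),
  aggregator = c("mean", "sum", "mean"),
  stringsAsFactors = FALSE
)

wb_channel_units <- function(channel) {
  .wb_channels$units[match(channel, .wb_channels$channel)]
}

wb_default_aggregator <- function(channel) {
  .wb_channels$aggregator[match(channel, .wb_channels$channel)]
}

#' Construct a single-channel physiological time series
#'
#' `bio_series` is the universal container consumed by every module: a
#' timestamped, strictly ordered, finite-valued series for one channel
#' (heart rate in bpm, steps per sampling interval, or interstitial glucose
#' in mg/dL). Missing observations are represented by absent samples, never
#' by sentinel values.
#'
#' @param time `POSIXct` timestamps (second resolution), strictly increasing.
#' @param value numeric sample values; all finite.
#' @param channel one of `"heart_rate"`, `"steps"`, `"glucose"`.
#' @param nominal_interval nominal sampling interval in seconds (> 0).
#' @param subject_id opaque subject identifier.
#' @return An object of class `bio_series`: a list with elements `time`,
#'   `value`, `channel`, `nominal_interval`, `subject_id`.
#' @export
bio_series <- function(time, value, channel, nominal_interval, subject_id = "anon") {
  channel <- match.arg(channel, .wb_channels$channel)
  if (!inherits(time, "POSIXct")) wb_contract_error("time must be POSIXct")
  value <- as.numeric(value)
  if (length(time) != length(value))
    wb_contract_error("time and value lengths differ")
  if (length(value) && any(!is.finite(value)))
    wb_contract_error("all values must be finite; drop missing samples instead")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0))
    wb_contract_error("timestamps must be strictly increasing")
  if (!is.numeric(nominal_interval) || length(nominal_interval) != 1 ||
      !is.finite(nominal_interval) || nominal_interval <= 0)
    wb_contract_error("nominal_interval must be a single positive number")
  structure(
    list(time = time, value = value, channel = channel,
         nominal_interval = as.numeric(nominal_interval),
         subject_id = as.character(subject_id)),
    class = "bio_series"
  )
}

#' @export
#' @method print bio_series
print.bio_series <- function(x, ...) {
  cat(sprintf("<bio_series> channel=%s [%s], n=%d, nominal interval=%gs\n",
              x$channel, wb_channel_units(x$channel), length(x$value),
              x$nominal_interval))
  if (length(x$value)) {
    cat(sprintf("  span: %s .. %s\n", format(x$time[1]),
                format(x$time[length(x$time)])))
    cat(sprintf("  value range: [%g, %g]\n", min(x$value), max(x$value)))
  }
  invisible(x)
}

#' @export
#' @method length bio_series
length.bio_series <- function(x) length(x$value)

series_tz <- function(series) {
  tz <- attr(series$time, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) "UTC" else tz[1]
}

series_epoch <- function(series) as.numeric(series$time)

series_dates <- function(series) as.Date(series$time, tz = series_tz(series))

# Subset a bio_series by index, preserving metadata.
series_subset <- function(series, idx) {
  bio_series(series$time[idx], series$value[idx], series$channel,
             series$nominal_interval, series$subject_id)
}

#' Plausibility bounds for a channel
#'
#' Defaults reflect physiological / sensor limits: heart rate 25--250 bpm,
#' steps 0--300 per minute, glucose 20--600 mg/dL.
#'
#' @param channel channel name.
#' @param low,high override the default bounds (`low < high`).
#' @return A list with elements `channel`, `low`, `high`.
#' @export
plausibility_bounds <- function(channel, low = NULL, high = NULL) {
  channel <- match.arg(channel, .wb_channels$channel)
  defaults <- list(heart_rate = c(25, 250), steps = c(0, 300),
                   glucose = c(20, 600))[[channel]]
  low  <- if (is.null(low)) defaults[1] else as.numeric(low)
  high <- if (is.null(high)) defaults[2] else as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    wb_contract_error("plausibility bounds require low < high")
  list(channel = channel, low = low, high = high)
}

#' Read a wearable time series from a long-format CSV
#'
#' Device-agnostic ingestion: any CSV with a timestamp column and a value
#' column. Rows with unparseable timestamps or non-numeric / non-finite
#' values are skipped with a warning count; duplicate timestamps are
#' collapsed to the mean of their values; rows are sorted by time.
#'
#' @param path CSV file path.
#' @param channel channel name (`"heart_rate"`, `"steps"`, `"glucose"`).
#' @param time_column,value_column column names (defaults `Time`, `Value`).
#' @param timezone timezone all timestamps are interpreted in / converted to.
#' @param nominal_interval nominal sampling interval in seconds (default: 60
#'   for heart rate and steps, 300 for glucose).
#' @return A [bio_series].
#' @export
read_series <- function(path, channel, time_column = "Time",
                        value_column = "Value", timezone = "UTC",
                        nominal_interval = NULL) {
  channel <- match.arg(channel, .wb_channels$channel)
  if (!file.exists(path)) wb_io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c(time_column, value_column) %in% names(df)))
    wb_contract_error(sprintf(
      "columns '%s' and '%s' must both be present in %s",
      time_column, value_column, path))
  tt <- parse_timestamps(as.character(df[[time_column]]), timezone)
  vv <- suppressWarnings(as.numeric(df[[value_column]]))
  ok <- !is.na(tt) & is.finite(vv)
  n_skipped <- sum(!ok)
  if (!any(ok)) wb_empty_input(sprintf("no parseable rows in %s", path))
  if (n_skipped > 0)
    warning(sprintf("%d unparseable row(s) skipped in %s", n_skipped, path),
            call. = FALSE)
  tt <- tt[ok]; vv <- vv[ok]
  o <- order(tt)
  tt <- tt[o]; vv <- vv[o]
  # Collapse duplicate timestamps to the mean (order-independent).
  if (anyDuplicated(tt)) {
    key <- as.numeric(tt)
    agg <- tapply(vv, key, mean)
    n_dup <- length(vv) - length(agg)
    message(sprintf("collapsed %d duplicate timestamp(s) by mean", n_dup))
    tt <- as.POSIXct(as.numeric(names(agg)), origin = "1970-01-01",
                     tz = timezone)
    vv <- unname(as.numeric(agg))
  }
  if (is.null(nominal_interval))
    nominal_interval <- if (channel == "glucose") 300 else 60
  message(sprintf("read %d sample(s) from %s", length(vv), path))
  bio_series(tt, vv, channel, nominal_interval)
}

# Accepts ISO 8601 "T" separators and plain "YYYY-mm-dd HH:MM:SS".
# Per-format strptime so individual malformed rows yield NA (to be
# skipped) instead of aborting the whole read.
parse_timestamps <- function(x, timezone) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = timezone)
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = timezone))
  }
  out
}

#' Write a series back to CSV
#'
#' Emits the same dialect [read_series] consumes (`Time,Value` header, ISO
#' 8601 timestamps). Values are printed with full double precision so a
#' read/write round trip is bit-exact.
#'
#' @param series a [bio_series].
#' @param path output path.
#' @param time_column,value_column header names.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, time_column = "Time",
                         value_column = "Value") {
  df <- data.frame(
    t = format(series$time, "%Y-%m-%dT%H:%M:%S"),
    v = sprintf("%.17g", series$value)
  )
  names(df) <- c(time_column, value_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop physiologically implausible samples
#'
#' @param series a [bio_series].
#' @param bounds a [plausibility_bounds] for the same channel.
#' @return A list with `series` (samples with `low <= value <= high`) and
#'   `rejected_count`.
#' @export
validate_series <- function(series, bounds = plausibility_bounds(series$channel)) {
  if (!identical(bounds$channel, series$channel))
    wb_contract_error(sprintf("bounds are for channel '%s', series is '%s'",
                              bounds$channel, series$channel))
  keep <- series$value >= bounds$low & series$value <= bounds$high
  list(series = series_subset(series, keep),
       rejected_count = sum(!keep))
}

#' Resample a series onto a uniform time grid
#'
#' Output timestamps are bin left edges of the uniform grid obtained by
#' floor-aligning the first sample's time to `interval`; each bin aggregates
#' the input samples falling in the half-open window `[t, t + interval)`.
#' Empty bins are absent (missing) for heart rate and glucose; for the steps
#' channel an empty bin inside the observed wear span means "no steps" and
#' is emitted as 0.
#'
#' @param series a [bio_series].
#' @param interval target grid interval in seconds.
#' @param aggregator `"mean"`, `"sum"` or `"median"` (default: channel's
#'   natural aggregator — sum for steps, mean otherwise).
#' @return A [bio_series] on the uniform grid with
#'   `nominal_interval = interval`.
#' @export
resample_uniform <- function(series, interval,
                             aggregator = wb_default_aggregator(series$channel)) {
  if (length(series) == 0) wb_empty_input("cannot resample an empty series")
  if (!is.numeric(interval) || interval <= 0)
    wb_contract_error("interval must be positive")
  aggregator <- match.arg(aggregator, c("mean", "sum", "median"))
  f <- switch(aggregator, mean = mean, sum = sum, median = stats::median)
  ep <- series_epoch(series)
  bin <- floor(ep / interval) * interval
  agg <- tapply(series$value, bin, f)
  bin_t <- as.numeric(names(agg))
  if (series$channel == "steps") {
    grid <- seq(min(bin_t), max(bin_t), by = interval)
    vals <- rep(0, length(grid))
    vals[match(bin_t, grid)] <- as.numeric(agg)
    bin_t <- grid
    agg <- vals
  }
  tz <- series_tz(series)
  bio_series(as.POSIXct(bin_t, origin = "1970-01-01", tz = tz),
             as.numeric(agg), series$channel, interval, series$subject_id)
}

#' Align two series onto a shared uniform grid
#'
#' Both series are resampled to `interval` (each with its channel's natural
#' aggregator) and only grid timestamps observed in *both* channels are
#' retained, yielding equal-length paired values.
#'
#' @param a,b two non-empty [bio_series].
#' @param interval shared grid interval in seconds.
#' @return A data frame with columns `time`, `value_a`, `value_b` and
#'   attributes `channel_a`, `channel_b`.
#' @export
align_series <- function(a, b, interval) {
  if (length(a) == 0 || length(b) == 0)
    wb_empty_input("align_series requires two non-empty series")
  ga <- resample_uniform(a, interval)
  gb <- resample_uniform(b, interval)
  common <- intersect(as.numeric(ga$time), as.numeric(gb$time))
  if (length(common) == 0)
    warning("series time ranges are disjoint; empty pairing", call. = FALSE)
  common <- sort(common)
  out <- data.frame(
    time = as.POSIXct(common, origin = "1970-01-01", tz = series_tz(a)),
    value_a = ga$value[match(common, as.numeric(ga$time))],
    value_b = gb$value[match(common, as.numeric(gb$time))]
  )
  attr(out, "channel_a") <- a$channel
  attr(out, "channel_b") <- b$channel
  out
}
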