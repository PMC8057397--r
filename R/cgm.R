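# Glycemic variability metrics for continuous glucose monitor traces.
# Every formula lives in exactly one operation so a metric definition can
# be revised locally. All SDs use the n-1 denominator; quartiles use
# linear interpolation.

#' Glucose target range
#'
#' Default 70--180 mg/dL (the clinical consensus range), boundary-inclusive.
#'
#' @param lower,upper range limits in mg/dL, `lower < upper`.
#' @return A list with `lower`, `upper`.
#' @export
range_config <- function(lower = 70, upper = 180) {
  if (lower >= upper) wb_contract_error("range requires lower < upper")
  list(lower = lower, upper = upper)
}

metric_row <- function(metric, value, units, reason = NA_character_) {
  present <- length(value) == 1 && is.finite(value)
  data.frame(metric = metric,
             value = if (present) as.numeric(value) else NA_real_,
             units = units, present = present,
             reason = if (present) NA_character_ else reason,
             stringsAsFactors = FALSE)
}

check_glucose <- function(trace) {
  if (!inherits(trace, "bio_series") || trace$channel != "glucose")
    wb_contract_error("trace must be a glucose bio_series")
  if (length(trace) == 0) wb_empty_input("glucose trace is empty")
}

#' Basic glucose statistics
#'
#' @param trace a glucose [bio_series].
#' @return Data frame of metrics `mean`, `median`, `min`, `max`, `q1`,
#'   `q3` (mg/dL).
#' @export
basic_stats <- function(trace) {
  check_glucose(trace)
  v <- trace$value
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  rbind(metric_row("mean",   mean(v), "mg/dL"),
        metric_row("median", stats::median(v), "mg/dL"),
        metric_row("min",    min(v), "mg/dL"),
        metric_row("max",    max(v), "mg/dL"),
        metric_row("q1",     q[1], "mg/dL"),
        metric_row("q3",     q[2], "mg/dL"))
}

#' Inter- and intraday glucose variability
#'
#' Interday SD/CV are computed over all samples; per-day SD and CV
#' (days with >= 2 samples) are aggregated across days by mean, median and
#' SD. Intraday metrics require >= 2 qualifying days.
#'
#' @param trace a glucose [bio_series].
#' @return Data frame of metrics `interday_sd`, `interday_cv`,
#'   `intraday_sd_mean`, `intraday_sd_median`, `intraday_sd_sd`,
#'   `intraday_cv_mean`, `intraday_cv_median`, `intraday_cv_sd`.
#' @export
variability_stats <- function(trace) {
  check_glucose(trace)
  v <- trace$value
  inter_sd <- sd0(v)
  inter_cv <- 100 * inter_sd / mean(v)
  d <- series_dates(trace)
  per_day <- split(v, d)
  per_day <- per_day[vapply(per_day, length, 1L) >= 2]
  out <- rbind(metric_row("interday_sd", inter_sd, "mg/dL"),
               metric_row("interday_cv", inter_cv, "%"))
  if (length(per_day) >= 2) {
    sds <- vapply(per_day, stats::sd, numeric(1))
    cvs <- 100 * sds / vapply(per_day, mean, numeric(1))
    out <- rbind(out,
      metric_row("intraday_sd_mean",   mean(sds), "mg/dL"),
      metric_row("intraday_sd_median", stats::median(sds), "mg/dL"),
      metric_row("intraday_sd_sd",     sd0(sds), "mg/dL"),
      metric_row("intraday_cv_mean",   mean(cvs), "%"),
      metric_row("intraday_cv_median", stats::median(cvs), "%"),
      metric_row("intraday_cv_sd",     sd0(cvs), "%"))
  } else {
    reason <- "requires >= 2 days with >= 2 samples each"
    for (nm in c("intraday_sd_mean", "intraday_sd_median", "intraday_sd_sd"))
      out <- rbind(out, metric_row(nm, NA_real_, "mg/dL", reason))
    for (nm in c("intraday_cv_mean", "intraday_cv_median", "intraday_cv_sd"))
      out <- rbind(out, metric_row(nm, NA_real_, "%", reason))
  }
  out
}

#' Time in / out of the target range
#'
#' @param trace a glucose [bio_series].
#' @param range a [range_config]; boundaries inclusive.
#' @return Data frame of metrics `tir_pct`, `tor_pct`, `por_pct`
#'   (percent outside range, identical to `tor_pct`), `mean_in_range`,
#'   `mean_out_range` (absent when the respective subset is empty).
#' @export
range_stats <- function(trace, range = range_config()) {
  check_glucose(trace)
  v <- trace$value
  inr <- v >= range$lower & v <= range$upper
  tir <- 100 * mean(inr)
  rbind(
    metric_row("tir_pct", tir, "%"),
    metric_row("tor_pct", 100 - tir, "%"),
    metric_row("por_pct", 100 - tir, "%"),
    metric_row("mean_in_range",
               if (any(inr)) mean(v[inr]) else NA_real_, "mg/dL",
               "no samples in range"),
    metric_row("mean_out_range",
               if (any(!inr)) mean(v[!inr]) else NA_real_, "mg/dL",
               "no samples out of range"))
}

# Symmetrizing blood-glucose risk transform (g in mg/dL).
bg_risk <- function(g) 1.509 * (log(g)^1.084 - 5.381)

#' Blood-glucose risk indices
#'
#' Uses the symmetrizing risk transform
#' `f(g) = 1.509 * ((ln g)^1.084 - 5.381)`; the low/high risk components
#' are `rl = 10 f^2` for `f < 0` (else 0) and `rh = 10 f^2` for `f > 0`
#' (else 0). LBGI and HBGI are the means of `rl` and `rh`; ADRR is the
#' mean over days of the daily maxima `max(rl) + max(rh)` (>= 2 days);
#' `j_index = 0.001 * (mean + SD)^2`.
#'
#' @param trace a glucose [bio_series] with strictly positive values.
#' @return Data frame of metrics `lbgi`, `hbgi`, `adrr`, `j_index`.
#' @export
risk_indices <- function(trace) {
  check_glucose(trace)
  v <- trace$value
  if (any(v <= 0))
    wb_contract_error("glucose values must be positive (validate first)")
  f <- bg_risk(v)
  rl <- ifelse(f < 0, 10 * f^2, 0)
  rh <- ifelse(f > 0, 10 * f^2, 0)
  d <- series_dates(trace)
  out <- rbind(metric_row("lbgi", mean(rl), "risk"),
               metric_row("hbgi", mean(rh), "risk"))
  if (length(unique(d)) >= 2) {
    daily <- vapply(split(seq_along(v), d),
                    function(i) max(rl[i]) + max(rh[i]), numeric(1))
    out <- rbind(out, metric_row("adrr", mean(daily), "risk"))
  } else {
    out <- rbind(out, metric_row("adrr", NA_real_, "risk",
                                 "requires >= 2 days"))
  }
  rbind(out, metric_row("j_index", 0.001 * (mean(v) + sd0(v))^2,
                        "mg^2/dL^2 x 1e-3"))
}

# Centered 9-point moving average (shorter windows at the edges).
smooth_ma9 <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(i) mean(v[max(1, i - 4):min(n, i + 4)]),
         numeric(1))
}

# Local extrema of a vector: compress equal-adjacent runs, take sign
# changes of consecutive differences; both endpoints are included.
local_extrema <- function(v) {
  keep <- c(TRUE, diff(v) != 0)
  idx <- which(keep)
  u <- v[idx]
  if (length(u) < 3) return(idx)
  s <- sign(diff(u))
  turn <- which(s[-1] != s[-length(s)]) + 1
  idx[c(1, turn, length(u))]
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Smoothed-extrema dialect: the trace is smoothed by a 9-point moving
#' average; consecutive local extrema of the smoothed trace whose absolute
#' difference exceeds `sd_multiplier` times the interday SD (of the raw
#' values) define qualifying excursions, and MAGE is the mean of their
#' amplitudes (both directions). Absent when no excursion qualifies.
#'
#' @param trace a glucose [bio_series] with >= 3 samples.
#' @param sd_multiplier excursion threshold in interday SDs (default 1).
#' @return Data frame with the single metric `mage`.
#' @export
mage <- function(trace, sd_multiplier = 1.0) {
  check_glucose(trace)
  v <- trace$value
  if (length(v) < 3) wb_contract_error("mage requires >= 3 samples")
  sm <- smooth_ma9(v)
  ext <- local_extrema(sm)
  amp <- abs(diff(sm[ext]))
  thr <- sd_multiplier * sd0(v)
  qual <- amp[amp > thr]
  metric_row("mage", if (length(qual)) mean(qual) else NA_real_, "mg/dL",
             "no excursions exceed the SD threshold")
}

#' Day-to-day glucose stability (MODD, CONGA24)
#'
#' Samples are paired with the sample 24 h earlier at matching clock time
#' (nearest match within +/- `tol_s` seconds). MODD is the mean absolute
#' paired difference; CONGA24 is the SD of the paired differences.
#'
#' @param trace a glucose [bio_series] spanning >= 2 days.
#' @param tol_s pairing tolerance in seconds (default 150 = +/- 2.5 min).
#' @return Data frame of metrics `modd`, `conga24`.
#' @export
day_to_day <- function(trace, tol_s = 150) {
  check_glucose(trace)
  ep <- series_epoch(trace)
  v <- trace$value
  diffs <- lagged_diffs(ep, v, 86400, tol_s)
  reason <- "requires samples pairable across 24 h"
  rbind(
    metric_row("modd", if (length(diffs)) mean(abs(diffs)) else NA_real_,
               "mg/dL", reason),
    metric_row("conga24", if (length(diffs) >= 2) sd0(diffs) else NA_real_,
               "mg/dL", reason))
}

# For each sample, the difference v(t) - v(t - lag) where a sample exists
# within tol of t - lag (nearest match).
lagged_diffs <- function(ep, v, lag_s, tol_s) {
  target <- ep - lag_s
  j <- findInterval(target, ep)
  cand <- cbind(j, j + 1)
  out <- numeric(0)
  for (i in seq_along(ep)) {
    ks <- cand[i, ]
    ks <- ks[ks >= 1 & ks <= length(ep)]
    if (!length(ks)) next
    k <- ks[which.min(abs(ep[ks] - target[i]))]
    if (abs(ep[k] - target[i]) <= tol_s) out <- c(out, v[i] - v[k])
  }
  out
}

#' Estimated HbA1c conversions
#'
#' Glucose management indicator `gmi_pct = 3.31 + 0.02392 * mean(g)` and
#' estimated A1c `ea1c_pct = (mean(g) + 46.7) / 28.7`, both in percent.
#'
#' @param trace a glucose [bio_series].
#' @return Data frame of metrics `gmi_pct`, `ea1c_pct`.
#' @export
hba1c_estimates <- function(trace) {
  check_glucose(trace)
  m <- mean(trace$value)
  rbind(metric_row("gmi_pct", 3.31 + 0.02392 * m, "%"),
        metric_row("ea1c_pct", (m + 46.7) / 28.7, "%"))
}

#' Full 28-metric glycemic report
#'
#' Union of [basic_stats] (6), [variability_stats] (8), [range_stats] (5),
#' [risk_indices] (4), [mage] (1), [day_to_day] (2) and [hba1c_estimates]
#' (2). Metrics whose preconditions are unmet are listed as absent with a
#' reason but still counted in the catalog.
#'
#' @param trace a glucose [bio_series].
#' @param range a [range_config].
#' @param sd_multiplier MAGE excursion threshold in SDs.
#' @return An object of class `cgm_report`: list with `metrics` (data
#'   frame `metric`, `value`, `units`, `present`, `reason`), `n_days`,
#'   `n_samples`.
#' @export
compute_all_metrics <- function(trace, range = range_config(),
                                sd_multiplier = 1.0) {
  check_glucose(trace)
  metrics <- rbind(basic_stats(trace),
                   variability_stats(trace),
                   range_stats(trace, range),
                   risk_indices(trace),
                   mage(trace, sd_multiplier),
                   day_to_day(trace),
                   hba1c_estimates(trace))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 n_days = length(unique(series_dates(trace))),
                 n_samples = length(trace)),
            class = "cgm_report")
}

#' @export
#' @method print cgm_report
print.cgm_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cgm_report> %d metrics (%d present), %d samples over %d day(s)\n",
              nrow(x$metrics), sum(x$metrics$present), x$n_samples, x$n_days))
  m <- x$metrics
  m$value <- signif(m$value, digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary cgm_report
summary.cgm_report <- function(object, ...) {
  m <- object$metrics
  cat(sprintf("Glycemic report: %d/%d metrics present\n",
              sum(m$present), nrow(m)))
  absent <- m[!m$present, c("metric", "reason")]
  if (nrow(absent)) {
    cat("Absent:\n")
    print(absent, row.names = FALSE)
  }
  invisible(object)
}

#' LOWESS-smoothed longitudinal glucose trend
#'
#' Locally weighted scatterplot smoothing of glucose against time,
#' evaluated at the input time points.
#'
#' @param trace a glucose [bio_series] with >= 10 samples.
#' @param frac smoother span in (0, 1].
#' @return A data frame `time`, `fitted` (mg/dL), of class `cgm_trend`.
#' @export
lowess_trend <- function(trace, frac = 0.15) {
  check_glucose(trace)
  if (length(trace) < 10)
    wb_degenerate("lowess_trend requires >= 10 samples")
  if (frac <= 0 || frac > 1) wb_contract_error("frac must be in (0, 1]")
  ep <- series_epoch(trace)
  fit <- stats::lowess(ep - ep[1], trace$value, f = frac)
  out <- data.frame(time = trace$time, fitted = fit$y)
  class(out) <- c("cgm_trend", "data.frame")
  attr(out, "raw") <- trace$value
  out
}

#' @export
plot.cgm_trend <- function(x, ...) {
  raw <- attr(x, "raw")
  graphics::plot(x$time, raw, pch = 16, cex = 0.4, col = "grey60",
                 xlab = "time", ylab = "glucose (mg/dL)", ...)
  graphics::lines(x$time, x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}
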