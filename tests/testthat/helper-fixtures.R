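# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive re-derivations (double loops, literal definitions)
# kept separate from the package implementations they check.

t0_utc <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

mk_series <- function(values, channel = "heart_rate", interval = 60,
                      start = t0_utc) {
  bio_series(start + interval * (seq_along(values) - 1), values, channel,
             interval)
}

write_series_csv <- function(times, values, path,
                             cols = c("Time", "Value")) {
  df <- data.frame(a = times, b = values)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# --- day-to-day oracle: all pairs exactly 24 h apart within tolerance ----
oracle_day_to_day <- function(times, values, tol_s = 150) {
  ep <- as.numeric(times)
  diffs <- c()
  for (i in seq_along(ep)) {
    best <- NA; bestgap <- Inf
    for (j in seq_along(ep)) {
      gap <- abs((ep[i] - ep[j]) - 86400)
      if (gap < bestgap) { bestgap <- gap; best <- j }
    }
    if (is.finite(bestgap) && bestgap <= tol_s)
      diffs <- c(diffs, values[i] - values[best])
  }
  list(modd = if (length(diffs)) mean(abs(diffs)) else NA_real_,
       conga24 = if (length(diffs) >= 2) stats::sd(diffs) else NA_real_)
}

# --- MAGE oracle: literal definition, independently coded ---------------
oracle_mage <- function(values, sd_multiplier = 1) {
  n <- length(values)
  sm <- numeric(n)
  for (i in seq_len(n)) sm[i] <- mean(values[max(1, i - 4):min(n, i + 4)])
  # drop repeats, then mark turning points by neighbour comparison
  u <- sm[c(TRUE, diff(sm) != 0)]
  if (length(u) < 2) return(NA_real_)
  ext <- c(u[1])
  for (k in 2:(length(u) - 1))
    if ((u[k] - u[k - 1]) * (u[k + 1] - u[k]) < 0) ext <- c(ext, u[k])
  ext <- c(ext, u[length(u)])
  amp <- abs(diff(ext))
  thr <- sd_multiplier * stats::sd(values)
  qual <- amp[amp > thr]
  if (length(qual)) mean(qual) else NA_real_
}

# --- RHR search oracle: naive full enumeration --------------------------
oracle_rhr_search <- function(hr_values, step_values, dates, config) {
  N <- length(hr_values)
  min_days <- if (!is.null(config$min_days)) config$min_days else
    min(3, length(unique(dates)))
  best <- NULL
  for (m in config$m_grid) for (n in config$n_grid) {
    rs <- vapply(seq_len(N), function(i)
      sum(step_values[max(1, i - m + 1):i]), numeric(1))
    keep <- rs <= n
    sv <- hr_values[keep]
    if (length(sv) == 0 || length(unique(dates[keep])) < min_days) {
      p <- Inf
    } else {
      target <- config$min_fraction * N
      short <- max(0, target - length(sv)) / target
      sdv <- function(x) if (length(x) < 2) 0 else stats::sd(x)
      p <- sdv(sv) + config$lambda * sdv(hr_values) * short
    }
    cand <- list(n = n, m = m, penalty = p,
                 rhr = if (length(sv)) stats::median(sv) else NA_real_)
    if (is.null(best) || p < best$penalty ||
        (p == best$penalty && (m < best$m || (m == best$m && n < best$n))))
      best <- cand
  }
  best
}

# IoU of one interval pair (used to cross-check interval_iou on toys)
simple_iou <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / ((a2 - a1) + (b2 - b1) - inter)
}

# A linearly separable epoch-feature fixture for classifier tests
separable_fixture <- function(n_per_class = 40, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  hh <- c(stats::runif(n_per_class, 0, 6),      # sleep: night hours
          stats::runif(n_per_class, 9, 21))     # wake: day hours
  feats <- data.frame(
    epoch = seq_len(n),
    hr_z = c(stats::rnorm(n_per_class, -2, 0.2),
             stats::rnorm(n_per_class, 2, 0.2)),
    hr_roll_mean = c(stats::rnorm(n_per_class, 55, 1),
                     stats::rnorm(n_per_class, 80, 1)),
    hr_roll_sd = stats::runif(n, 0.5, 1.5),
    step_roll_sum = c(rep(0, n_per_class),
                      stats::runif(n_per_class, 100, 500)),
    tod_sin = sin(2 * pi * hh / 24), tod_cos = cos(2 * pi * hh / 24))
  labels <- factor(rep(c("likely_sleep", "likely_wake"), each = n_per_class),
                   levels = c("likely_sleep", "likely_wake", "unlabeled"))
  list(features = feats, labels = labels)
}

series_subset_public <- function(s, idx) {
  bio_series(s$time[idx], s$value[idx], s$channel, s$nominal_interval)
}
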