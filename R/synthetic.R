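# Ground-truth-bearing signal generators. Every generator is a pure
# function of its parameter object (seed included): identical inputs give
# bit-identical outputs.

parse_clock <- function(x) {
  # "HH:MM" -> hours since midnight
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(p[1]) + as.numeric(p[2]) / 60
}

#' Parameters for the heart-rate + step simulator
#'
#' The simulated day has a single 24-h circadian sinusoid peaking at 15:00
#' (trough 03:00), a nightly sleep window with depressed heart rate, and a
#' bout schedule of stepped activity with elevated heart rate. With the
#' default 23:00--07:00 sleep window and this circadian phase the median of
#' the non-bout heart rate equals `rhr_true` by construction, making
#' `rhr_true` a well-defined recovery target.
#'
#' The default bout schedule mimics ordinary ambulatory behaviour: light
#' movement bouts (10 min at 25 steps/min, +12 bpm) roughly every 90
#' minutes across the waking day, plus one daily exercise bout (30 min at
#' 90 steps/min, +40 bpm) in the late afternoon; placements are jittered
#' per seed.
#'
#' @param rhr_true true resting heart rate, bpm.
#' @param circadian_amp amplitude of the circadian sinusoid, bpm.
#' @param sleep_windows list of `c(start, end)` clock times ("HH:MM") per
#'   day; windows may cross midnight.
#' @param sleep_drop heart-rate depression inside sleep windows, bpm
#'   (keep `< rhr_true` to avoid implausible values).
#' @param bout_schedule data frame `start_min` (minutes from simulation
#'   start), `duration_min`, `steps_per_min`, `hr_rise`; `NULL` builds the
#'   schedule named by `bout_profile`.
#' @param bout_profile `"ambulatory"` (default: light bouts through the
#'   waking day plus one exercise bout — the realistic daily-life profile
#'   the sleep detector is aimed at) or `"exercise"` (two discrete daily
#'   exercise bouts only — the protocol used for resting-heart-rate
#'   recovery studies, where heart rate is elevated only during stepped
#'   exercise).
#' @param noise_sd i.i.d. Gaussian noise SD, bpm.
#' @param days number of simulated days.
#' @param seed RNG seed.
#' @param start simulation start date ("YYYY-MM-DD").
#' @param tz timezone.
#' @return An object of class `hr_sim_params`.
#' @export
hr_sim_params <- function(rhr_true = 60, circadian_amp = 3,
                          sleep_windows = list(c("23:00", "07:00")),
                          sleep_drop = 5, bout_schedule = NULL,
                          bout_profile = c("ambulatory", "exercise"),
                          noise_sd = 3, days = 7, seed = 1,
                          start = "2020-01-01", tz = "UTC") {
  bout_profile <- match.arg(bout_profile)
  if (rhr_true <= 0) wb_contract_error("rhr_true must be positive")
  if (noise_sd < 0) wb_contract_error("noise_sd must be >= 0")
  if (days < 1) wb_contract_error("days must be >= 1")
  if (sleep_drop >= rhr_true)
    wb_contract_error("sleep_drop must be < rhr_true (safe range)")
  structure(list(rhr_true = rhr_true, circadian_amp = circadian_amp,
                 sleep_windows = sleep_windows, sleep_drop = sleep_drop,
                 bout_schedule = bout_schedule, bout_profile = bout_profile,
                 noise_sd = noise_sd, days = days, seed = seed,
                 start = start, tz = tz),
            class = "hr_sim_params")
}

# Bouts are placed inside the waking period implied by the (first) sleep
# window, so shifted sleep schedules shift the activity pattern with them.
default_bout_schedule <- function(days, seed, profile = "ambulatory",
                                  sleep_window = c("23:00", "07:00")) {
  set.seed(seed + 104729L)
  wake_start <- parse_clock(sleep_window[2])           # hours, clock
  wake_len <- (parse_clock(sleep_window[1]) - wake_start) %% 24
  if (wake_len == 0) wake_len <- 24
  rows <- list()
  # day -1 included so waking periods that cross midnight are covered from
  # simulation start; bouts entirely before t = 0 are dropped below
  for (d in seq(-1, days - 1)) {
    base <- d * 1440
    if (profile == "ambulatory") {
      # light bouts every ~90 min across the waking period, leaving a
      # 2.25-h slot about two-thirds through it free for the exercise bout
      ex_h <- wake_start + 0.65 * wake_len
      slots <- seq(wake_start + 1, wake_start + wake_len - 1.5, by = 1.5)
      slots <- slots[abs(slots - ex_h) > 1.1]
      for (h in slots) {
        start <- base + h * 60 + sample(-15:15, 1)
        rows[[length(rows) + 1]] <- c(start, 10, 25, 12)
      }
      rows[[length(rows) + 1]] <- c(base + (ex_h - 0.5) * 60 + sample(0:45, 1),
                                    30, 90, 40)
    } else {
      # two discrete daily exercise bouts, morning-ish and afternoon-ish
      # relative to the waking period
      h1 <- wake_start + 0.20 * wake_len
      h2 <- wake_start + 0.65 * wake_len
      rows[[length(rows) + 1]] <- c(base + h1 * 60 + sample(-45:45, 1),
                                    45, 100, 45)
      rows[[length(rows) + 1]] <- c(base + h2 * 60 + sample(-30:30, 1),
                                    30, 90, 40)
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("start_min", "duration_min", "steps_per_min", "hr_rise")
  df <- df[df$start_min + df$duration_min > 0, ]
  df[order(df$start_min), ]
}

#' Simulate paired heart-rate and step series with known ground truth
#'
#' Minute grid over `days` days. Heart rate is
#' `rhr_true + circadian_amp * sin(2*pi*(h - 9)/24) - sleep_drop` inside
#' sleep windows `+ hr_rise` inside bouts, plus Gaussian noise; steps are 0
#' except inside bouts.
#'
#' @param params an [hr_sim_params].
#' @return A list: `hr` and `steps` ([bio_series] on the minute grid) and
#'   `truth` (list with `rhr_true`, `sleep_intervals` data frame
#'   (`start`, `end` POSIXct), `bout_minutes` count, `bout_schedule`).
#' @export
simulate_hr_steps <- function(params = hr_sim_params()) {
  stopifnot(inherits(params, "hr_sim_params"))
  tz <- params$tz
  t0 <- as.POSIXct(paste(params$start, "00:00:00"), tz = tz)
  n_min <- params$days * 1440
  tt <- t0 + 60 * (seq_len(n_min) - 1)
  hod <- ((as.numeric(tt) - as.numeric(t0)) / 3600) %% 24
  circ <- sin(2 * pi * (hod - 9) / 24)

  # sleep indicator from per-day clock windows (may cross midnight)
  sleep <- rep(FALSE, n_min)
  intervals <- list()
  day_min <- ((seq_len(n_min) - 1) %% 1440) / 60  # clock hours
  day_idx <- (seq_len(n_min) - 1) %/% 1440
  for (w in params$sleep_windows) {
    s <- parse_clock(w[1]); e <- parse_clock(w[2])
    if (s < e) {
      sleep <- sleep | (day_min >= s & day_min < e)
      for (d in 0:(params$days - 1))
        intervals[[length(intervals) + 1]] <-
          c(d * 1440 + s * 60, d * 1440 + e * 60)
    } else {
      sleep <- sleep | (day_min >= s | day_min < e)
      # window crossing midnight: night d runs from day d into day d+1
      for (d in 0:(params$days - 1))
        intervals[[length(intervals) + 1]] <-
          c(d * 1440 + s * 60, (d + 1) * 1440 + e * 60)
      # leading partial window on day 0
      intervals[[length(intervals) + 1]] <- c(0, parse_clock(w[2]) * 60)
    }
  }
  iv <- do.call(rbind, intervals)
  iv <- iv[iv[, 1] < n_min, , drop = FALSE]
  iv[, 2] <- pmin(iv[, 2], n_min)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  sleep_intervals <- data.frame(start = t0 + 60 * iv[, 1],
                                end = t0 + 60 * iv[, 2])

  bouts <- params$bout_schedule
  if (is.null(bouts))
    bouts <- default_bout_schedule(params$days, params$seed,
                                   params$bout_profile,
                                   params$sleep_windows[[1]])
  bout_rise <- numeric(n_min)
  steps_v <- numeric(n_min)
  b_end <- bouts$start_min + bouts$duration_min
  if (nrow(bouts) > 1 && any(bouts$start_min[-1] < b_end[-nrow(bouts)]))
    wb_contract_error("bout schedule contains overlapping bouts")
  for (i in seq_len(nrow(bouts))) {
    idx <- which(seq_len(n_min) - 1 >= bouts$start_min[i] &
                   seq_len(n_min) - 1 < b_end[i])
    bout_rise[idx] <- bouts$hr_rise[i]
    steps_v[idx] <- bouts$steps_per_min[i]
  }

  set.seed(params$seed)
  noise <- if (params$noise_sd > 0) stats::rnorm(n_min, 0, params$noise_sd)
           else numeric(n_min)
  hr_v <- params$rhr_true + params$circadian_amp * circ -
    params$sleep_drop * sleep + bout_rise + noise

  list(
    hr = bio_series(tt, hr_v, "heart_rate", 60),
    steps = bio_series(tt, steps_v, "steps", 60),
    truth = list(rhr_true = params$rhr_true,
                 sleep_intervals = sleep_intervals,
                 bout_minutes = sum(steps_v > 0),
                 bout_schedule = bouts)
  )
}

#' Parameters for the CGM simulator
#'
#' @param baseline fasting glucose, mg/dL.
#' @param meal_times clock times ("HH:MM") of daily meal excursions.
#' @param excursion_amp peak excursion height above baseline, mg/dL.
#' @param rise_min linear rise time to peak, minutes.
#' @param decay_min exponential decay time constant after the peak, minutes.
#' @param noise_sd sensor noise SD, mg/dL.
#' @param days number of simulated days.
#' @param interval_s sampling interval, seconds (default 300 = 5 min).
#' @param seed RNG seed.
#' @param start start date.
#' @param tz timezone.
#' @return An object of class `cgm_sim_params`.
#' @export
cgm_sim_params <- function(baseline = 100,
                           meal_times = c("08:00", "13:00", "19:00"),
                           excursion_amp = 60, rise_min = 30, decay_min = 60,
                           noise_sd = 5, days = 14, interval_s = 300,
                           seed = 1, start = "2020-01-01", tz = "UTC") {
  if (baseline < 20 || baseline > 600)
    wb_contract_error("baseline must lie within glucose plausibility bounds")
  if (excursion_amp < 0) wb_contract_error("excursion_amp must be >= 0")
  if (noise_sd < 0) wb_contract_error("noise_sd must be >= 0")
  structure(list(baseline = baseline, meal_times = meal_times,
                 excursion_amp = excursion_amp, rise_min = rise_min,
                 decay_min = decay_min, noise_sd = noise_sd, days = days,
                 interval_s = interval_s, seed = seed, start = start,
                 tz = tz),
            class = "cgm_sim_params")
}

# Meal excursion kernel at minutes-since-meal u (vectorized):
# linear rise 0 -> amp over rise_min, then amp * exp(-(u - rise)/decay).
meal_kernel <- function(u, amp, rise_min, decay_min) {
  out <- numeric(length(u))
  up <- u >= 0 & u < rise_min
  dn <- u >= rise_min
  out[up] <- amp * u[up] / rise_min
  out[dn] <- amp * exp(-(u[dn] - rise_min) / decay_min)
  out
}

#' Simulate a CGM glucose trace with known ground truth
#'
#' Glucose on a uniform grid is the baseline plus one excursion kernel per
#' meal (linear rise to the peak, exponential decay after it) plus i.i.d.
#' Gaussian sensor noise.
#'
#' @param params a [cgm_sim_params].
#' @return A list: `trace` (a glucose [bio_series]) and `truth` (list with
#'   `noiseless` values, `mean`, `min`, `max` and `tir_pct` of the
#'   noiseless grid against the 70--180 mg/dL consensus range).
#' @export
simulate_cgm <- function(params = cgm_sim_params()) {
  stopifnot(inherits(params, "cgm_sim_params"))
  t0 <- as.POSIXct(paste(params$start, "00:00:00"), tz = params$tz)
  n <- params$days * 86400 / params$interval_s
  tt <- t0 + params$interval_s * (seq_len(n) - 1)
  minute <- (as.numeric(tt) - as.numeric(t0)) / 60
  g <- rep(params$baseline, n)
  for (d in 0:(params$days - 1)) for (mt in params$meal_times) {
    u <- minute - (d * 1440 + parse_clock(mt) * 60)
    g <- g + meal_kernel(u, params$excursion_amp, params$rise_min,
                         params$decay_min)
  }
  set.seed(params$seed)
  noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd)
           else numeric(n)
  trace <- bio_series(tt, g + noise, "glucose", params$interval_s)
  list(trace = trace,
       truth = list(noiseless = g, mean = mean(g), min = min(g),
                    max = max(g),
                    tir_pct = 100 * mean(g >= 70 & g <= 180)))
}

#' Remove a known fraction of samples (controlled missingness)
#'
#' @param series a [bio_series].
#' @param pattern `"random"` (uniform without replacement) or `"block"`
#'   (contiguous runs).
#' @param fraction fraction of samples to remove, in `[0, 1)`;
#'   `floor(fraction * n)` samples are removed.
#' @param seed RNG seed.
#' @param blocks number of contiguous runs for `pattern = "block"`.
#' @return A list: `series` (retained samples) and `mask` (integer indices
#'   of the removed samples in the input) plus `removed_times` (POSIXct).
#' @export
degrade_missing <- function(series, pattern = c("random", "block"),
                            fraction, seed = 1, blocks = 3L) {
  pattern <- match.arg(pattern)
  if (fraction < 0 || fraction >= 1)
    wb_contract_error("fraction must be in [0, 1)")
  n <- length(series)
  n_remove <- floor(fraction * n)
  set.seed(seed)
  if (n_remove == 0) {
    mask <- integer(0)
  } else if (pattern == "random") {
    mask <- sort(sample.int(n, n_remove))
  } else {
    blocks <- max(1L, min(as.integer(blocks), n_remove))
    lens <- diff(round(seq(0, n_remove, length.out = blocks + 1)))
    mask <- integer(0)
    for (len in lens[lens > 0]) {
      placed <- FALSE
      for (try in 1:1000) {
        s <- sample.int(n - len + 1, 1)
        cand <- s:(s + len - 1)
        if (!any(cand %in% mask)) { mask <- c(mask, cand); placed <- TRUE; break }
      }
      if (!placed) {  # fall back: first free run of this length
        free <- setdiff(seq_len(n), mask)
        runs <- split(free, cumsum(c(1, diff(free) != 1)))
        for (rn in runs) if (length(rn) >= len) {
          mask <- c(mask, rn[seq_len(len)]); break
        }
      }
    }
    mask <- sort(mask)
  }
  keep <- setdiff(seq_len(n), mask)
  list(series = series_subset(series, keep), mask = mask,
       removed_times = series$time[mask])
}
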