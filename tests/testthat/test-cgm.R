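mk_glucose <- function(values, interval = 300, start = t0_utc)
  mk_series(values, channel = "glucose", interval = interval, start = start)

two_day_square <- function() {
  # alternating 90/150 every 2 h for 2 days on the 5-min grid
  n <- 2 * 288
  phase <- ((seq_len(n) - 1) %/% 24) %% 2
  mk_glucose(ifelse(phase == 0, 90, 150))
}

test_that("basic statistics match hand values and degenerate limits", {
  b <- basic_stats(mk_glucose(c(80, 100, 120)))
  expect_equal(b$value[b$metric == "mean"], 100)
  expect_equal(b$value[b$metric == "median"], 100)

  cst <- basic_stats(mk_glucose(rep(100, 10)))
  expect_true(all(cst$value == 100))

  one <- basic_stats(mk_glucose(150))
  expect_true(all(one$value == 150))
})

test_that("variability metrics follow their definitions", {
  cst <- variability_stats(mk_glucose(rep(100, 600)))
  expect_true(all(cst$value[cst$present] == 0))

  # two identical days: zero spread of per-day SDs
  d1 <- rep(c(90, 110), 144)
  two <- mk_glucose(c(d1, d1))
  v <- variability_stats(two)
  expect_equal(v$value[v$metric == "intraday_sd_sd"], 0)
  expect_equal(v$value[v$metric == "intraday_sd_mean"], sd(d1))

  # hand-checked interday CV on a small fixture
  vals <- c(rep(100, 59), 130)
  v2 <- variability_stats(mk_glucose(vals))
  expect_equal(v2$value[v2$metric == "interday_sd"], sd(vals))
  expect_equal(v2$value[v2$metric == "interday_cv"],
               100 * sd(vals) / mean(vals))

  # under two qualifying days the intraday family is absent with a reason
  short <- variability_stats(mk_glucose(rep(100, 12)))
  expect_false(any(short$present[grepl("intraday", short$metric)]))
  expect_true(all(!is.na(short$reason[grepl("intraday", short$metric)])))
})

test_that("range metrics are boundary-inclusive and sum to 100", {
  r <- range_stats(mk_glucose(rep(100, 50)))
  expect_equal(r$value[r$metric == "tir_pct"], 100)
  expect_equal(r$value[r$metric == "tor_pct"], 0)

  r2 <- range_stats(mk_glucose(c(60, 100, 200, 100)))
  expect_equal(r2$value[r2$metric == "tir_pct"], 50)
  expect_equal(r2$value[r2$metric == "mean_out_range"], 130)
  expect_equal(r2$value[r2$metric == "por_pct"],
               r2$value[r2$metric == "tor_pct"])

  r3 <- range_stats(mk_glucose(rep(100, 5)), range_config(99, 101))
  expect_equal(r3$value[r3$metric == "tir_pct"], 100)

  set.seed(1)
  r4 <- range_stats(mk_glucose(runif(100, 40, 400)))
  expect_equal(r4$value[r4$metric == "tir_pct"] +
                 r4$value[r4$metric == "tor_pct"], 100)
})

test_that("risk indices apply the glucose risk transform", {
  # constant 100 mg/dL: f < 0 so HBGI 0 and LBGI = 10 f(100)^2
  f100 <- 1.509 * (log(100)^1.084 - 5.381)
  r <- risk_indices(mk_glucose(rep(100, 600)))
  expect_equal(r$value[r$metric == "hbgi"], 0)
  expect_equal(r$value[r$metric == "lbgi"], 10 * f100^2, tolerance = 1e-12)
  expect_equal(round(r$value[r$metric == "lbgi"], 2), 0.48)

  # constant 150: j_index = 0.001 * 150^2
  r2 <- risk_indices(mk_glucose(rep(150, 600)))
  expect_equal(r2$value[r2$metric == "j_index"], 22.5)

  # the transform's fixed point zeroes both indices
  g0 <- exp(5.381^(1 / 1.084))
  r3 <- risk_indices(mk_glucose(rep(g0, 600)))
  expect_equal(r3$value[r3$metric == "lbgi"], 0, tolerance = 1e-15)
  expect_equal(r3$value[r3$metric == "hbgi"], 0, tolerance = 1e-15)

  one_day <- risk_indices(mk_glucose(rep(100, 100)))
  expect_false(one_day$present[one_day$metric == "adrr"])
})

test_that("MAGE matches the brute-force oracle and trivial limits", {
  expect_false(mage(mk_glucose(rep(100, 100)))$present)

  sq <- two_day_square()
  m <- mage(sq)
  expect_true(m$present)
  expect_equal(m$value, 60)
  expect_equal(m$value, oracle_mage(sq$value), tolerance = 1e-9)

  # pure noise: excursions stay near the noise scale
  set.seed(12)
  noise <- mk_glucose(rnorm(576, 120, 10))
  mn <- mage(noise)
  expect_equal(mn$value, oracle_mage(noise$value), tolerance = 1e-9)
  if (mn$present) expect_lte(mn$value, 2 * 10 + 10)
})

test_that("MODD and CONGA24 match the pairing oracle", {
  d1 <- rep(c(90, 110), 144)
  two <- mk_glucose(c(d1, d1))
  dd <- day_to_day(two)
  expect_equal(dd$value[dd$metric == "modd"], 0)
  expect_equal(dd$value[dd$metric == "conga24"], 0)

  off <- mk_glucose(c(d1, d1 + 10))
  dd2 <- day_to_day(off)
  expect_equal(dd2$value[dd2$metric == "modd"], 10)
  expect_equal(dd2$value[dd2$metric == "conga24"], 0)

  # 2 days x 4 samples at matched clock times, hand-built
  tt <- t0_utc + c(0, 6, 12, 18, 24, 30, 36, 42) * 3600
  vv <- c(100, 120, 110, 90, 105, 140, 100, 95)
  tr <- bio_series(tt, vv, "glucose", 300)
  dd3 <- day_to_day(tr)
  o <- oracle_day_to_day(tt, vv)
  expect_equal(dd3$value[dd3$metric == "modd"], o$modd, tolerance = 1e-9)
  expect_equal(dd3$value[dd3$metric == "modd"],
               mean(abs(c(105 - 100, 140 - 120, 100 - 110, 95 - 90))))
  expect_equal(dd3$value[dd3$metric == "conga24"], o$conga24,
               tolerance = 1e-9)

  # random 2-day trace against the oracle
  set.seed(5)
  rnd <- mk_glucose(rnorm(576, 120, 15))
  dd4 <- day_to_day(rnd)
  o4 <- oracle_day_to_day(rnd$time, rnd$value)
  expect_equal(dd4$value[dd4$metric == "modd"], o4$modd, tolerance = 1e-9)
  expect_equal(dd4$value[dd4$metric == "conga24"], o4$conga24,
               tolerance = 1e-9)

  expect_false(any(day_to_day(mk_glucose(rep(100, 10)))$present))
})

test_that("HbA1c conversions follow the published affine forms", {
  h <- hba1c_estimates(mk_glucose(rep(150, 10)))
  expect_equal(h$value[h$metric == "gmi_pct"], 6.898)
  expect_equal(h$value[h$metric == "ea1c_pct"], (150 + 46.7) / 28.7)

  h2 <- hba1c_estimates(mk_glucose(rep(180, 10)))
  expect_gt(h2$value[h2$metric == "gmi_pct"],
            h$value[h$metric == "gmi_pct"])
})

test_that("the full report enumerates 28 metrics with reasons for absences", {
  sim <- simulate_cgm(cgm_sim_params(seed = 2))
  rep <- compute_all_metrics(sim$trace)
  expect_equal(nrow(rep$metrics), 28)
  expect_equal(anyDuplicated(rep$metrics$metric), 0)
  expect_gte(sum(rep$metrics$present), 25)
  expect_equal(rep$n_days, 14)

  cst <- compute_all_metrics(mk_glucose(rep(100, 600)))
  m <- cst$metrics
  expect_equal(m$value[m$metric == "interday_sd"], 0)
  expect_equal(m$value[m$metric == "tir_pct"], 100)
  expect_false(m$present[m$metric == "mage"])

  one_day <- compute_all_metrics(mk_glucose(rep(c(90, 130), 144)))
  m1 <- one_day$metrics
  expect_equal(nrow(m1), 28)
  absent <- c("modd", "conga24", "adrr", "intraday_sd_mean")
  expect_false(any(m1$present[m1$metric %in% absent]))
  expect_true(all(!is.na(m1$reason[m1$metric %in% absent])))
})

test_that("metrics respect offset, duplication and percent invariants", {
  # structured trace whose excursion amplitudes sit far from the MAGE
  # threshold, so the offset invariance is not probed at a discontinuity
  set.seed(7)
  n <- 4 * 288
  tr <- mk_glucose(120 + 40 * sin(2 * pi * (0:(n - 1)) / 96) +
                     rnorm(n, 0, 3))
  base <- compute_all_metrics(tr)$metrics
  shifted <- compute_all_metrics(
    bio_series(tr$time, tr$value + 25, "glucose", 300))$metrics
  unchanged <- c("interday_sd", "intraday_sd_mean", "mage", "modd",
                 "conga24")
  for (nm in unchanged)
    expect_equal(shifted$value[shifted$metric == nm],
                 base$value[base$metric == nm], tolerance = 1e-9)
  for (nm in c("mean", "median", "min", "max"))
    expect_equal(shifted$value[shifted$metric == nm],
                 base$value[base$metric == nm] + 25, tolerance = 1e-9)
  expect_equal(shifted$value[shifted$metric == "gmi_pct"],
               base$value[base$metric == "gmi_pct"] + 0.02392 * 25,
               tolerance = 1e-9)

  pct <- base$metric %in% c("tir_pct", "tor_pct", "por_pct")
  expect_true(all(base$value[pct] >= 0 & base$value[pct] <= 100))

  # duplicating every sample (interleaved +1 s) leaves sample statistics
  # unchanged
  dup_t <- sort(c(tr$time, tr$time + 1))
  dup_v <- rep(tr$value, each = 2)
  dup <- compute_all_metrics(bio_series(dup_t, dup_v, "glucose", 300))$metrics
  for (nm in c("mean", "median", "min", "max", "tir_pct", "gmi_pct"))
    expect_equal(dup$value[dup$metric == nm],
                 base$value[base$metric == nm], tolerance = 1e-9)
  # n-1 SDs shift only at O(1/n) under duplication
  expect_equal(dup$value[dup$metric == "interday_sd"],
               base$value[base$metric == "interday_sd"], tolerance = 1e-3)
})

test_that("LOWESS trend preserves constants, lines and reduces noise", {
  cst <- lowess_trend(mk_glucose(rep(120, 50)))
  expect_true(all(abs(cst$fitted - 120) < 1e-9))

  lin <- mk_glucose(100 + 0.1 * (0:99))
  fit <- lowess_trend(lin, frac = 1.0)
  expect_lt(max(abs(fit$fitted - lin$value)), 1e-6)

  set.seed(3)
  n <- 576
  truth <- 120 + 30 * sin(2 * pi * (0:(n - 1)) / 288)
  noisy <- mk_glucose(truth + rnorm(n, 0, 15))
  sm <- lowess_trend(noisy, frac = 0.15)
  rmse <- function(x) sqrt(mean((x - truth)^2))
  expect_lt(rmse(sm$fitted), rmse(noisy$value))

  expect_error(lowess_trend(mk_glucose(rep(100, 5))),
               class = "wearbio_degenerate_smoothing")
})
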