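sim_night <- function(seed = 21, days = 3)
  simulate_hr_steps(hr_sim_params(seed = seed, days = days))

test_that("heuristic seeds fall inside true sleep and respect run lengths", {
  sim <- sim_night()
  cfg <- sleep_config(seed = 21)
  hl <- heuristic_label(sim$hr, sim$steps, cfg)
  expect_setequal(levels(hl$labels),
                  c("likely_sleep", "likely_wake", "unlabeled"))
  idx <- which(hl$labels == "likely_sleep")
  mid <- as.numeric(hl$epochs$start[idx]) + cfg$epoch_s / 2
  tr <- sim$truth$sleep_intervals
  inside <- vapply(mid, function(t)
    any(t >= as.numeric(tr$start) & t < as.numeric(tr$end)), logical(1))
  expect_gte(mean(inside), 0.95)
  expect_gt(sum(hl$labels == "likely_wake"), 0)

  # all-wake degenerate input is untrainable
  hr <- mk_series(rep(70, 2 * 1440))
  st <- mk_series(rep(20, 2 * 1440), channel = "steps")
  expect_error(heuristic_label(hr, st, cfg),
               class = "wearbio_untrainable_labels")

  # under 24 h of overlap is insufficient
  expect_error(heuristic_label(mk_series(rep(60, 100)),
                               mk_series(rep(0, 100), channel = "steps"),
                               cfg),
               class = "wearbio_insufficient_data")
})

test_that("a 90-minute quiet run is too short to seed sleep", {
  # flat day with one 90-min quiet low-HR dip: run_min 120 rejects it
  n <- 2 * 1440
  hr_v <- rep(70, n); st_v <- rep(0, n)
  dip <- 601:690
  hr_v[dip] <- 50
  st_v[setdiff(seq_len(n), dip)] <- rep(c(rep(0, 50), rep(3, 10)),
                                        length.out = n - length(dip))
  # add a genuine long sleep block so labeling is trainable
  night <- 1200:1500
  hr_v[night] <- 50; st_v[night] <- 0
  hl <- heuristic_label(mk_series(hr_v), mk_series(st_v, channel = "steps"),
                        sleep_config())
  dip_epochs <- which(as.numeric(hl$epochs$start) %in%
                        (as.numeric(t0_utc) + 60 * (dip - 1)))
  expect_false(any(hl$labels[dip_epochs] == "likely_sleep"))
})

test_that("epoch features encode clock phase and degrade gracefully", {
  sim <- sim_night()
  cfg <- sleep_config()
  hl <- heuristic_label(sim$hr, sim$steps, cfg)
  feats <- extract_features(hl$epochs, cfg)
  expect_equal(feats$tod_sin^2 + feats$tod_cos^2, rep(1, nrow(feats)))
  ep6 <- which(format(hl$epochs$start, "%H:%M") == "06:00")[1]
  row <- feats[feats$epoch == ep6, ]
  h <- 6 + (cfg$epoch_s / 2) / 3600
  expect_equal(row$tod_sin, sin(2 * pi * h / 24))
  expect_equal(row$tod_cos, cos(2 * pi * h / 24))

  # constant heart rate: zero-variance z-scores are defined as 0
  hr <- mk_series(rep(60, 2 * 1440))
  st <- mk_series(rep(0, 2 * 1440), channel = "steps")
  ep <- data.frame(start = t0_utc + 300 * (0:575),
                   mean_hr = 60, step_sum = 0, n_hr = 5)
  f2 <- extract_features(ep, cfg)
  expect_true(all(f2$hr_z == 0))
  expect_true(all(f2$step_roll_sum == 0))
})

test_that("classifier training selects by CV and reproduces separable labels", {
  fx <- separable_fixture()
  tr <- train_select_classifier(fx$features, fx$labels, sleep_config(seed = 3))
  expect_equal(unname(tr$cv_report["logistic"]), 1.0)
  expect_equal(unname(tr$cv_report["svm_radial"]), 1.0)
  # tie on CV accuracy prefers the linear logistic model
  expect_equal(tr$model$type, "logistic")

  cls <- classify_epochs(tr$model, fx$features)
  expect_true(all(cls$prob >= 0 & cls$prob <= 1))
  want <- fx$labels[fx$features$epoch] == "likely_sleep"
  expect_equal(cls$sleep, as.vector(want))

  # predictions are invariant to epoch ordering
  perm <- sample(nrow(fx$features))
  cls_p <- classify_epochs(tr$model, fx$features[perm, ])
  expect_equal(cls_p$prob[order(cls_p$epoch)], cls$prob[order(cls$epoch)])

  # single-class labels are untrainable
  one <- fx$labels
  one[one == "likely_wake"] <- "likely_sleep"
  expect_error(train_select_classifier(fx$features, one, sleep_config()),
               class = "wearbio_untrainable_labels")
})

test_that("random labels on identical features score at chance", {
  n <- 80
  feats <- data.frame(epoch = 1:n, hr_z = 0, hr_roll_mean = 60,
                      hr_roll_sd = 1, step_roll_sum = 0,
                      tod_sin = 0.5, tod_cos = sqrt(0.75))
  set.seed(99)
  labels <- factor(sample(c("likely_sleep", "likely_wake"), n, TRUE),
                   levels = c("likely_sleep", "likely_wake", "unlabeled"))
  tr <- train_select_classifier(feats, labels, sleep_config(seed = 99))
  expect_lte(abs(tr$cv_report["logistic"] - 0.5), 0.1)
  expect_lte(abs(tr$cv_report["svm_radial"] - 0.5), 0.1)
})

test_that("episode smoothing filters, merges and prunes", {
  cfg <- sleep_config()
  ep <- data.frame(start = t0_utc + 300 * (0:287), mean_hr = 60,
                   step_sum = 0, n_hr = 5)

  # isolated sleep epoch is median-filtered away
  x <- rep(FALSE, 288); x[100] <- TRUE
  expect_equal(nrow(smooth_to_episodes(ep[1:5, ], c(FALSE, FALSE, TRUE,
                                                    FALSE, FALSE), cfg)), 0)

  # 96 consecutive sleep epochs give one 480-min episode
  x <- rep(FALSE, 288); x[50:145] <- TRUE
  e <- smooth_to_episodes(ep, x, cfg)
  expect_equal(nrow(e), 1)
  expect_equal(e$duration_min, 480)

  # two 90-min runs with a 20-min gap merge (merge_gap 30)
  x <- rep(FALSE, 288); x[10:27] <- TRUE; x[32:49] <- TRUE
  e2 <- smooth_to_episodes(ep, x, cfg)
  expect_equal(nrow(e2), 1)
  expect_equal(as.numeric(e2$end - e2$start, units = "mins"), 200)

  # a 40-min run is dropped (min_episode 60)
  x <- rep(FALSE, 288); x[10:17] <- TRUE
  expect_equal(nrow(smooth_to_episodes(ep, x, cfg)), 0)
})

test_that("detected episodes recover the true schedule, even shifted", {
  for (sched in list(c("23:00", "07:00"), c("08:00", "16:00"))) {
    sim <- simulate_hr_steps(hr_sim_params(seed = 33,
                                           sleep_windows = list(sched)))
    res <- detect_sleep(sim$hr, sim$steps, sleep_config(seed = 33))
    expect_s3_class(res, "sleep_result")
    iou <- interval_iou(res$episodes, sim$truth$sleep_intervals)
    expect_gte(iou, 0.85)
    # episodes are ordered and non-overlapping, within the recording span
    expect_true(all(diff(as.numeric(res$episodes$start)) > 0))
    expect_true(all(res$episodes$end[-nrow(res$episodes)] <=
                      res$episodes$start[-1]))
    expect_lte(sum(res$episodes$duration_min),
               as.numeric(max(sim$hr$time) - min(sim$hr$time),
                          units = "mins"))
  }
})

test_that("the pipeline is deterministic and time-shift equivariant", {
  sim <- sim_night(seed = 8, days = 7)
  cfg <- sleep_config(seed = 8)
  r1 <- detect_sleep(sim$hr, sim$steps, cfg)
  r2 <- detect_sleep(sim$hr, sim$steps, cfg)
  expect_identical(r1$episodes, r2$episodes)
  expect_identical(r1$cv_report, r2$cv_report)

  shift <- 6 * 3600
  hr_s <- bio_series(sim$hr$time + shift, sim$hr$value, "heart_rate", 60)
  st_s <- bio_series(sim$steps$time + shift, sim$steps$value, "steps", 60)
  r3 <- detect_sleep(hr_s, st_s, cfg)
  expect_equal(nrow(r3$episodes), nrow(r1$episodes))
  expect_lte(max(abs(as.numeric(r3$episodes$start) -
                       as.numeric(r1$episodes$start) - shift)), cfg$epoch_s)
  expect_lte(max(abs(as.numeric(r3$episodes$end) -
                       as.numeric(r1$episodes$end) - shift)), cfg$epoch_s)
})

test_that("interval IoU agrees with the single-pair closed form", {
  a <- data.frame(start = t0_utc, end = t0_utc + 3600)
  b <- data.frame(start = t0_utc + 1800, end = t0_utc + 5400)
  expect_equal(interval_iou(a, b), simple_iou(0, 3600, 1800, 5400))
  expect_equal(interval_iou(a, a), 1)
  d <- data.frame(start = t0_utc + 7200, end = t0_utc + 10800)
  expect_equal(interval_iou(a, d), 0)
})
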