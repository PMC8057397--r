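# Sleep/wake detection from heart rate + actigraphy: heuristic seed
# labels, candidate classifiers selected by cross-validated balanced
# accuracy, epoch classification, and episode smoothing.

#' Configuration for sleep detection
#'
#' @param epoch_s epoch length in seconds (default 300).
#' @param hr_quantile heart-rate quantile below which an epoch can seed a
#'   likely-sleep run (default 0.40).
#' @param run_min minimum zero-step low-heart-rate run, minutes (120).
#' @param wake_step_min step count per epoch that marks likely wake (50).
#' @param cv_folds stratified cross-validation folds (5).
#' @param smooth_width median-filter width in epochs (5, odd).
#' @param merge_gap sleep runs closer than this many minutes merge (30).
#' @param min_episode minimum episode duration in minutes (60).
#' @param min_hr_coverage minimum fraction of expected heart-rate samples
#'   for an epoch to be feature-eligible (0.5).
#' @param sedentary_wake_window minutes: a zero-step epoch whose heart rate
#'   is not depressed (at or above the `hr_quantile` threshold) is seeded
#'   as likely wake when any steps occur within this window (60).
#' @param seed RNG seed for fold assignment and classifier fitting.
#' @return An object of class `sleep_config`.
#' @export
sleep_config <- function(epoch_s = 300, hr_quantile = 0.40, run_min = 120,
                         wake_step_min = 50, cv_folds = 5, smooth_width = 5,
                         merge_gap = 30, min_episode = 60,
                         min_hr_coverage = 0.5, sedentary_wake_window = 60,
                         seed = 1) {
  vals <- c(epoch_s, run_min, wake_step_min, cv_folds, smooth_width,
            merge_gap, min_episode)
  if (any(vals <= 0)) wb_contract_error("all sleep_config sizes must be positive")
  if (hr_quantile <= 0 || hr_quantile >= 1)
    wb_contract_error("hr_quantile must be in (0, 1)")
  if (smooth_width %% 2 == 0)
    wb_contract_error("smooth_width must be odd")
  structure(list(epoch_s = epoch_s, hr_quantile = hr_quantile,
                 run_min = run_min, wake_step_min = wake_step_min,
                 cv_folds = cv_folds, smooth_width = smooth_width,
                 merge_gap = merge_gap, min_episode = min_episode,
                 min_hr_coverage = min_hr_coverage,
                 sedentary_wake_window = sedentary_wake_window, seed = seed),
            class = "sleep_config")
}

# Aggregate aligned hr/steps series into epochs. Epochs with fewer than
# min_hr_coverage of expected heart-rate samples get mean_hr = NA.
build_epochs <- function(hr, steps, config) {
  epoch_s <- config$epoch_s
  hr_ep <- series_epoch(hr); st_ep <- series_epoch(steps)
  t0 <- floor(min(hr_ep[1], st_ep[1]) / epoch_s) * epoch_s
  t1 <- floor(max(hr_ep[length(hr_ep)], st_ep[length(st_ep)]) / epoch_s) * epoch_s
  grid <- seq(t0, t1, by = epoch_s)
  hr_bin <- floor(hr_ep / epoch_s) * epoch_s
  st_bin <- floor(st_ep / epoch_s) * epoch_s
  mean_hr <- rep(NA_real_, length(grid))
  n_hr <- integer(length(grid))
  agg_m <- tapply(hr$value, hr_bin, mean)
  agg_n <- tapply(hr$value, hr_bin, length)
  i <- match(as.numeric(names(agg_m)), grid)
  mean_hr[i] <- as.numeric(agg_m)
  n_hr[i] <- as.integer(agg_n)
  expected <- epoch_s / hr$nominal_interval
  mean_hr[n_hr < config$min_hr_coverage * expected] <- NA_real_
  step_sum <- rep(0, length(grid))
  agg_s <- tapply(steps$value, st_bin, sum)
  step_sum[match(as.numeric(names(agg_s)), grid)] <- as.numeric(agg_s)
  data.frame(
    start = as.POSIXct(grid, origin = "1970-01-01", tz = series_tz(hr)),
    mean_hr = mean_hr, step_sum = step_sum, n_hr = n_hr)
}

#' Heuristic likely-sleep / likely-wake seed labels
#'
#' Likely sleep: epochs inside maximal runs of at least `run_min` minutes
#' in which every epoch has zero steps and mean heart rate below the
#' subject's `hr_quantile` epoch-level quantile. Likely wake: epochs with
#' `step_sum >= wake_step_min`, plus sedentary-wake epochs satisfying a
#' dual gate — mean heart rate not depressed (at or above the
#' `hr_quantile` threshold) *and* stepped activity somewhere within
#' `sedentary_wake_window` minutes. Everything else is unlabeled.
#'
#' Both seed classes must cover their state with high precision: sleep
#' seeds come from long quiet HR-depressed runs, and wake seeds must
#' include quiet sitting as well as movement, otherwise a classifier
#' trained on them only ever sees wake during exercise and places its
#' boundary far above resting heart rate.
#'
#' @param hr,steps [bio_series] with >= 24 h of overlapping data.
#' @param config a [sleep_config].
#' @return A list: `epochs` (data frame `start`, `mean_hr`, `step_sum`,
#'   `n_hr`) and `labels` (factor with levels `likely_sleep`,
#'   `likely_wake`, `unlabeled`).
#' @export
heuristic_label <- function(hr, steps, config = sleep_config()) {
  if (length(hr) == 0 || length(steps) == 0)
    wb_empty_input("hr and steps must be non-empty")
  overlap <- min(max(series_epoch(hr)), max(series_epoch(steps))) -
    max(min(series_epoch(hr)), min(series_epoch(steps)))
  if (overlap < 86400)
    wb_insufficient("sleep detection requires >= 24 h of overlapping data")
  ep <- build_epochs(hr, steps, config)
  q <- stats::quantile(ep$mean_hr, config$hr_quantile, na.rm = TRUE,
                       names = FALSE)
  candidate <- ep$step_sum == 0 & !is.na(ep$mean_hr) & ep$mean_hr < q
  run_epochs <- ceiling(config$run_min * 60 / config$epoch_s)
  lab <- rep("unlabeled", nrow(ep))
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= run_epochs)
      lab[starts[k]:ends[k]] <- "likely_sleep"
  lab[ep$step_sum >= config$wake_step_min] <- "likely_wake"
  # sedentary wake: not HR-depressed and within reach of stepped activity
  wk <- ceiling(config$sedentary_wake_window * 60 / config$epoch_s)
  n_ep <- nrow(ep)
  near_steps <- vapply(seq_len(n_ep), function(i)
    sum(ep$step_sum[max(1, i - wk):min(n_ep, i + wk)]) > 0, logical(1))
  lab[lab == "unlabeled" & !is.na(ep$mean_hr) & ep$mean_hr >= q &
        near_steps] <- "likely_wake"
  if (!any(lab == "likely_sleep") || !any(lab == "likely_wake"))
    wb_untrainable("heuristic produced zero likely-sleep or likely-wake epochs")
  list(epochs = ep,
       labels = factor(lab, levels = c("likely_sleep", "likely_wake",
                                       "unlabeled")))
}

#' Per-epoch classifier features
#'
#' For each epoch: `hr_z` (epoch mean heart rate z-scored against all
#' epoch means; 0 when the SD is 0), `hr_roll_mean` and `hr_roll_sd` over
#' +/- 30 min of epoch means, `step_roll_sum` over +/- 30 min, and
#' `tod_sin`/`tod_cos` encoding 24-h clock phase of the epoch midpoint.
#' Epochs with insufficient heart-rate data (see
#' `sleep_config$min_hr_coverage`) are excluded and counted.
#'
#' @param epochs epoch data frame from [heuristic_label].
#' @param config a [sleep_config].
#' @return A data frame with `epoch` (row index into `epochs`) and the six
#'   features; attribute `excluded` gives the number of dropped epochs.
#' @export
extract_features <- function(epochs, config = sleep_config()) {
  if (nrow(epochs) == 0) wb_empty_input("no epochs")
  mh <- epochs$mean_hr
  mu <- mean(mh, na.rm = TRUE); s <- stats::sd(mh[!is.na(mh)])
  if (!is.finite(s) || s == 0) s <- Inf  # hr_z := 0 under zero variance
  w <- ceiling(1800 / config$epoch_s)   # +/- 30 min in epochs
  n <- nrow(epochs)
  roll <- function(i, x, f) {
    win <- x[max(1, i - w):min(n, i + w)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else f(win)
  }
  hr_roll_mean <- vapply(seq_len(n), roll, numeric(1), x = mh, f = mean)
  hr_roll_sd   <- vapply(seq_len(n), roll, numeric(1), x = mh, f = sd0)
  step_roll    <- vapply(seq_len(n), roll, numeric(1), x = epochs$step_sum,
                         f = sum)
  mid <- epochs$start + config$epoch_s / 2
  tz <- attr(epochs$start, "tzone"); if (is.null(tz)) tz <- "UTC"
  hh <- as.numeric(format(mid, "%H", tz = tz)) +
    as.numeric(format(mid, "%M", tz = tz)) / 60 +
    as.numeric(format(mid, "%S", tz = tz)) / 3600
  feat <- data.frame(
    epoch = seq_len(n),
    hr_z = ifelse(is.na(mh), NA_real_, (mh - mu) / s),
    hr_roll_mean = hr_roll_mean, hr_roll_sd = hr_roll_sd,
    step_roll_sum = step_roll,
    tod_sin = sin(2 * pi * hh / 24), tod_cos = cos(2 * pi * hh / 24))
  keep <- stats::complete.cases(feat)
  excluded <- sum(!keep)
  feat <- feat[keep, ]
  if (nrow(feat) == 0) wb_no_features("every epoch lacks usable features")
  attr(feat, "excluded") <- excluded
  feat
}

feature_cols <- c("hr_z", "hr_roll_mean", "hr_roll_sd", "step_roll_sum",
                  "tod_sin", "tod_cos")

# Scale non-circular columns by their training SD (SD 0 -> divisor 1).
# The tod sin/cos pair is left unscaled so the classifier treats clock
# phase rotation-invariantly.
fit_scaling <- function(X) {
  sc <- rep(1, ncol(X)); names(sc) <- colnames(X)
  for (j in c("hr_roll_mean", "hr_roll_sd", "step_roll_sum")) {
    s <- stats::sd(X[, j])
    sc[j] <- if (is.finite(s) && s > 0) s else 1
  }
  sc
}

apply_scaling <- function(X, sc) sweep(X, 2, sc, "/")

balanced_accuracy <- function(truth, pred) {
  levs <- levels(truth)
  mean(vapply(levs, function(l) {
    i <- truth == l
    if (!any(i)) return(NA_real_)
    mean(pred[i] == l)
  }, numeric(1)), na.rm = TRUE)
}

# Inverse-frequency class weights: both candidates optimize a balanced
# objective, matching the balanced-accuracy selection metric.
class_weights <- function(y) {
  n <- table(y)
  c(wake = as.numeric(sum(n) / (2 * n["wake"])),
    sleep = as.numeric(sum(n) / (2 * n["sleep"])))
}

fit_candidate <- function(type, X, y, seed) {
  # y: factor with levels c("wake", "sleep"); returns prob of sleep
  w <- class_weights(y)
  if (all(apply(X, 2, stats::sd) == 0)) {
    # no usable information: coin-flip probability for any input
    return(list(type = type, fit = NULL,
                prob = function(newX) rep(0.5, nrow(newX))))
  }
  if (type == "logistic") {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = 0.01, standardize = FALSE,
                          weights = as.numeric(w[as.character(y)]))
    list(type = type, fit = fit,
         prob = function(newX)
           as.numeric(stats::predict(fit, newX, type = "response")))
  } else {
    set.seed(seed)
    fit <- e1071::svm(X, y, kernel = "radial", scale = FALSE,
                      class.weights = w)
    # symmetric logistic squashing of the decision score: monotone,
    # in [0, 1], and maps the margin (score 0) to probability 0.5 so the
    # 0.5 label threshold coincides with the balanced decision boundary
    list(type = type, fit = fit,
         prob = function(newX) {
           pr <- stats::predict(fit, newX, decision.values = TRUE)
           f <- as.numeric(attr(pr, "decision.values"))
           if (startsWith(colnames(attr(pr, "decision.values"))[1], "wake"))
             f <- -f
           1 / (1 + exp(-2 * f))
         })
  }
}

#' Train candidate sleep classifiers and select by cross-validation
#'
#' Two candidates are trained on the heuristically labeled epochs only: a
#' ridge-regularized linear logistic model and a radial-kernel
#' maximum-margin classifier (Platt-calibrated probabilities). The winner
#' is the model with the higher mean stratified `cv_folds`-fold
#' cross-validated balanced accuracy (ties prefer the logistic model) and
#' is refit on all labeled epochs.
#'
#' @param features feature data frame from [extract_features].
#' @param labels factor from [heuristic_label] aligned with
#'   `features$epoch`.
#' @param config a [sleep_config].
#' @return A list: `model` (class `sleep_model`) and `cv_report` (named
#'   numeric of per-candidate CV balanced accuracies).
#' @export
train_select_classifier <- function(features, labels,
                                    config = sleep_config()) {
  lab <- as.character(labels)[features$epoch]
  sel <- lab %in% c("likely_sleep", "likely_wake")
  y <- factor(ifelse(lab[sel] == "likely_sleep", "sleep", "wake"),
              levels = c("wake", "sleep"))
  if (nlevels(droplevels(y)) < 2)
    wb_untrainable("both label classes are required for training")
  if (min(table(y)) < config$cv_folds)
    wb_untrainable(sprintf("each class needs >= %d labeled epochs",
                           config$cv_folds))
  X <- as.matrix(features[sel, feature_cols])
  sc <- fit_scaling(X)
  Xs <- apply_scaling(X, sc)

  # stratified, seeded fold assignment
  set.seed(config$seed)
  fold <- integer(nrow(Xs))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(config$cv_folds), length(i)))
  }
  types <- c("logistic", "svm_radial")
  cv <- vapply(types, function(tp) {
    accs <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- fold != k
      m <- fit_candidate(tp, Xs[tr, , drop = FALSE], droplevels(y[tr]),
                         seed = config$seed + k)
      p <- m$prob(Xs[!tr, , drop = FALSE])
      balanced_accuracy(y[!tr], factor(ifelse(p >= 0.5, "sleep", "wake"),
                                       levels = c("wake", "sleep")))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  # tolerance rule: keep the simpler, better-calibrated linear model
  # unless the kernel machine is clearly better in cross-validation
  winner <- if (cv["svm_radial"] > cv["logistic"] + 0.01) "svm_radial"
            else "logistic"
  final <- fit_candidate(winner, Xs, y, seed = config$seed)
  model <- structure(list(type = winner, inner = final, scaling = sc,
                          cv_report = cv),
                     class = "sleep_model")
  list(model = model, cv_report = cv)
}

#' @export
#' @method print sleep_model
print.sleep_model <- function(x, ...) {
  cat(sprintf("<sleep_model> %s (CV balanced accuracy: logistic %.3f, svm %.3f)\n",
              x$type, x$cv_report["logistic"], x$cv_report["svm_radial"]))
  invisible(x)
}

#' Classify epochs with a trained sleep model
#'
#' @param model a `sleep_model` from [train_select_classifier].
#' @param features feature data frame from [extract_features]; records
#'   with missing fields are excluded with a warning.
#' @return A data frame `epoch`, `prob` (sleep probability in `[0, 1]`),
#'   `sleep` (logical, `prob >= 0.5`).
#' @export
classify_epochs <- function(model, features) {
  if (nrow(features) == 0) wb_empty_input("no features to classify")
  ok <- stats::complete.cases(features[, feature_cols])
  if (any(!ok))
    warning(sprintf("%d feature record(s) with missing fields excluded",
                    sum(!ok)), call. = FALSE)
  feats <- features[ok, ]
  X <- apply_scaling(as.matrix(feats[, feature_cols]), model$scaling)
  p <- model$inner$prob(X)
  data.frame(epoch = feats$epoch, prob = p, sleep = p >= 0.5)
}

#' Smooth per-epoch sleep labels into episodes
#'
#' A running median of width `smooth_width` removes isolated flips; runs
#' of sleep separated by less than `merge_gap` minutes are merged;
#' episodes shorter than `min_episode` minutes are dropped.
#'
#' @param epochs epoch data frame (time-ordered).
#' @param sleep logical vector, one element per row of `epochs`.
#' @param config a [sleep_config].
#' @return A data frame of class `sleep_episodes`: `start`, `end`,
#'   `duration_min`, `mean_hr`; episodes are non-overlapping and ordered.
#' @export
smooth_to_episodes <- function(epochs, sleep, config = sleep_config()) {
  stopifnot(nrow(epochs) == length(sleep))
  x <- as.numeric(sleep)
  if (length(x) >= config$smooth_width)
    x <- as.numeric(stats::runmed(x, config$smooth_width) >= 0.5)
  r <- rle(x == 1)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    gap_epochs <- config$merge_gap * 60 / config$epoch_s
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1 < gap_epochs)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  if (nrow(runs)) {
    dur <- (runs$end - runs$start + 1) * config$epoch_s / 60
    runs <- runs[dur >= config$min_episode, , drop = FALSE]
  }
  out <- data.frame(
    start = epochs$start[runs$start],
    end = epochs$start[runs$end] + config$epoch_s,
    duration_min = (runs$end - runs$start + 1) * config$epoch_s / 60,
    mean_hr = vapply(seq_len(nrow(runs)), function(i)
      mean(epochs$mean_hr[runs$start[i]:runs$end[i]], na.rm = TRUE),
      numeric(1)))
  class(out) <- c("sleep_episodes", "data.frame")
  out
}

#' Detect sleep episodes from heart rate and steps
#'
#' Full pipeline: (read, validate, resample when paths are given) then
#' heuristic labeling, feature extraction, classifier training/selection,
#' epoch classification, and episode smoothing. Deterministic for a fixed
#' `config$seed`.
#'
#' @param hr,steps [bio_series] objects, or paths to long-format CSVs.
#' @param config a [sleep_config].
#' @param timezone timezone used when reading CSV paths.
#' @param out_json optional path for a JSON report.
#' @return An object of class `sleep_result`: `episodes`
#'   ([smooth_to_episodes] output), `cv_report`, `model_type`, `counts`
#'   (per-stage epoch counts), `config`.
#' @export
detect_sleep <- function(hr, steps, config = sleep_config(),
                         timezone = "UTC", out_json = NULL) {
  if (is.character(hr))
    hr <- with_stage("read", read_series(hr, "heart_rate",
                                         timezone = timezone))
  if (is.character(steps))
    steps <- with_stage("read", read_series(steps, "steps",
                                            timezone = timezone))
  hr <- with_stage("validate", validate_series(hr))$series
  steps <- with_stage("validate", validate_series(steps))$series
  hl <- with_stage("heuristic_label", heuristic_label(hr, steps, config))
  feats <- with_stage("extract_features",
                      extract_features(hl$epochs, config))
  tr <- with_stage("train_select",
                   train_select_classifier(feats, hl$labels, config))
  cls <- with_stage("classify", classify_epochs(tr$model, feats))
  sleep_flag <- rep(FALSE, nrow(hl$epochs))
  sleep_flag[cls$epoch] <- cls$sleep
  episodes <- with_stage("smooth",
                         smooth_to_episodes(hl$epochs, sleep_flag, config))
  res <- structure(list(
    episodes = episodes,
    cv_report = tr$cv_report,
    model_type = tr$model$type,
    model = tr$model,
    counts = c(epochs = nrow(hl$epochs),
               likely_sleep = sum(hl$labels == "likely_sleep"),
               likely_wake = sum(hl$labels == "likely_wake"),
               feature_excluded = attr(feats, "excluded"),
               classified_sleep = sum(cls$sleep),
               episodes = nrow(episodes)),
    config = config
  ), class = "sleep_result")
  if (!is.null(out_json)) {
    rep <- list(
      model = res$model_type,
      cv_balanced_accuracy = as.list(res$cv_report),
      counts = as.list(res$counts),
      episodes = data.frame(
        start = format(episodes$start, "%Y-%m-%dT%H:%M:%S"),
        end = format(episodes$end, "%Y-%m-%dT%H:%M:%S"),
        duration_min = episodes$duration_min,
        mean_hr = episodes$mean_hr))
    atomic_write_json(rep, out_json)
  }
  res
}

#' @export
#' @method print sleep_result
print.sleep_result <- function(x, ...) {
  cat(sprintf("<sleep_result> %d episode(s); model %s (CV bal. acc. %.3f)\n",
              nrow(x$episodes), x$model_type, max(x$cv_report)))
  if (nrow(x$episodes)) {
    df <- x$episodes
    df$start <- format(df$start); df$end <- format(df$end)
    print(as.data.frame(df), row.names = FALSE)
  }
  invisible(x)
}

#' Intersection-over-union of two time interval sets
#'
#' Fidelity measure for episode recovery: total intersection length over
#' total union length of two sets of (start, end) intervals.
#'
#' @param a,b data frames with `start`, `end` (POSIXct or numeric).
#' @return IoU in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  to_mat <- function(d) cbind(as.numeric(d$start), as.numeric(d$end))
  A <- to_mat(a); B <- to_mat(b)
  len <- function(M) sum(M[, 2] - M[, 1])
  inter <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    inter <- inter + max(0, min(A[i, 2], B[j, 2]) - max(A[i, 1], B[j, 1]))
  union <- len(A) + len(B) - inter
  if (union <= 0) return(0)
  inter / union
}
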