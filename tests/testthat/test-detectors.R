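# Window, minute and 10-minute detectors.

test_that("gait and rest windows are separated by a simulator-trained model", {
  cfg <- pipeline_config()
  prof <- cached_profile()
  gait <- simulate_session(
    protocol_script(list(activity_segment("gait", 60))), seed = 21)
  rest <- simulate_session(
    protocol_script(list(activity_segment("rest", 60))), seed = 22)
  run_flags <- function(ses) {
    run_pipeline(ses$stream, cfg, prof)$windows
  }
  expect_gte(mean(run_flags(gait)$walking), 0.9)
  expect_lte(mean(run_flags(rest)$walking), 0.1)
})

test_that("freezing windows are flagged and clean gait is not", {
  cfg <- pipeline_config()
  prof <- cached_profile()
  fog <- simulate_session(
    protocol_script(list(activity_segment("fog", 60))), seed = 23)
  gait <- simulate_session(
    protocol_script(list(activity_segment("gait", 60))), seed = 24)
  wf <- run_pipeline(fog$stream, cfg, prof)$windows
  wg <- run_pipeline(gait$stream, cfg, prof)$windows
  expect_gte(mean(wf$fog), 0.8)
  expect_lte(mean(wg$fog), 0.05)
})

test_that("degenerate windows with a negative-bias model are not flagged", {
  m <- svm_model(matrix(0, 1, 2), alpha = 1, y = 1, sigma = 1, b = -2,
                 feature_names = c("mean_x", "std_x"),
                 scaler = list(mean = c(0, 0), sd = c(1, 1)))
  expect_false(detect_gait(c(mean_x = 100, std_x = 100), m))
  # degenerate zero-bias model on a zero window: margin 0 -> not flagged
  m0 <- svm_model(matrix(0, 1, 1), alpha = 1, y = 1, sigma = 1, b = -1,
                  feature_names = "std_x",
                  scaler = list(mean = 0, sd = 1))
  expect_false(detect_fog(c(std_x = 0), m0))
})

test_that("fluidity is near 1 for a pure harmonic, low for noise, 0 for zero", {
  n <- 128
  t <- (0:(n - 1)) / 40
  clean <- make_window(sin(2 * pi * 1.875 * t))  # exactly bin 6
  expect_gt(fluidity_score(clean), 0.95)
  withr::local_seed(31)
  noise_scores <- replicate(20, fluidity_score(make_window(rnorm(n))))
  expect_lt(mean(noise_scores), 0.3)
  expect_equal(fluidity_score(make_window(rep(0, n))), 0)
})

test_that("cadence tracks the scripted step frequency and doubles with it", {
  run_cadence <- function(f_step, seed) {
    ses <- simulate_session(protocol_script(list(
      activity_segment("gait", 60, params = list(step_freq = f_step)))),
      seed = seed)
    filt <- apply_filter(ses$stream, design_lowpass(15, 40))$stream
    wins <- segment_windows(filt, window_spec())
    cads <- vapply(wins, function(w)
      cadence_estimate(stft(w$x, 40))$cadence, numeric(1))
    median(cads, na.rm = TRUE)
  }
  c2 <- run_cadence(2.0, 32)
  expect_equal(c2, 120, tolerance = 5 / 120)
  c1 <- run_cadence(1.0, 33)
  expect_equal(c2 / c1, 2, tolerance = 0.1)

  # rest window: no credible locomotor peak -> undefined
  withr::local_seed(34)
  expect_true(is.na(cadence_estimate(stft(rnorm(128, sd = 0.03), 40))$cadence))
})

decisions_df <- function(walking, fluidity = NA, dysk = FALSE,
                         cadence = NA) {
  n <- length(walking)
  data.frame(window = seq_len(n), start = (seq_len(n) - 1) * 64,
             time_s = 0, walking = walking, fog = FALSE,
             fluidity = rep_len(fluidity, n), dysk = rep_len(dysk, n),
             cadence = rep_len(cadence, n), step_length = NA_real_,
             step_velocity = NA_real_)
}

test_that("minute aggregation enforces the gait quorum and thresholds", {
  prof <- patient_profile(NULL, NULL, theta_p = 0.5)
  # all-gait minute, fluid gait -> valid, not bradykinetic
  mo <- minute_aggregate(decisions_df(rep(TRUE, 37), fluidity = 0.8), prof)
  expect_true(mo$valid)
  expect_false(mo$brady)
  expect_equal(mo$brady_score, 0.8)
  # fluidity below threshold -> bradykinetic
  expect_true(minute_aggregate(decisions_df(rep(TRUE, 37), fluidity = 0.3),
                               prof)$brady)
  # below quorum -> invalid, symptoms undefined
  mo5 <- minute_aggregate(
    decisions_df(c(rep(TRUE, 5), rep(FALSE, 32)), fluidity = 0.3), prof)
  expect_false(mo5$valid)
  expect_true(is.na(mo5$brady))
  # exactly at quorum -> valid
  expect_true(minute_aggregate(
    decisions_df(c(rep(TRUE, 10), rep(FALSE, 27)), fluidity = 0.9),
    prof)$valid)
  # empty minute -> invalid
  expect_false(minute_aggregate(NULL, prof)$valid)
})

test_that("dyskinetic minutes require the configured share of non-gait windows", {
  prof <- patient_profile(NULL, NULL, theta_p = 0.5)
  w <- c(rep(TRUE, 17), rep(FALSE, 20))
  dy <- c(rep(FALSE, 17), rep(TRUE, 10), rep(FALSE, 10))  # exactly 50%
  expect_true(minute_aggregate(decisions_df(w, fluidity = 0.8, dysk = dy),
                               prof)$dysk)
  dy2 <- c(rep(FALSE, 17), rep(TRUE, 9), rep(FALSE, 11))
  expect_false(minute_aggregate(decisions_df(w, fluidity = 0.8, dysk = dy2),
                                prof)$dysk)
})

make_minute <- function(brady, dysk = FALSE, valid = TRUE) {
  structure(list(minute = 0L, valid = valid, n_windows = 37L, n_gait = 20L,
                 brady = brady, brady_score = 0.5, dysk = dysk,
                 cadence = 110, step_length = NA, step_velocity = NA),
            class = "minute_output")
}

test_that("the 10-minute state rule covers OFF, ON and undetermined", {
  off <- onoff_state(replicate(10, make_minute(TRUE), simplify = FALSE))
  expect_identical(off$state, "OFF")
  on <- onoff_state(c(replicate(7, make_minute(FALSE), simplify = FALSE),
                      replicate(3, make_minute(FALSE, dysk = TRUE),
                                simplify = FALSE)))
  expect_identical(on$state, "ON")
  und <- onoff_state(c(replicate(4, make_minute(TRUE), simplify = FALSE),
                       replicate(6, make_minute(FALSE), simplify = FALSE)))
  expect_identical(und$state, "undetermined")
  novalid <- onoff_state(replicate(10, make_minute(TRUE, valid = FALSE),
                                   simplify = FALSE))
  expect_identical(novalid$state, "undetermined")
})

test_that("a scripted OFF-to-ON fluctuation is recovered blockwise", {
  # 10 OFF blocks then 10 ON blocks at the minute-decision level, with
  # noisy per-minute fluidity around the condition means
  withr::local_seed(35)
  prof <- patient_profile(NULL, NULL, theta_p = 0.5)
  mk_block <- function(state) {
    mins <- lapply(1:10, function(i) {
      fl <- if (state == "OFF") rnorm(1, 0.35, 0.05) else rnorm(1, 0.7, 0.05)
      minute_aggregate(decisions_df(rep(TRUE, 37), fluidity = fl), prof)
    })
    onoff_state(mins)$state
  }
  states <- c(replicate(10, mk_block("OFF")), replicate(10, mk_block("ON")))
  truth <- rep(c("OFF", "ON"), each = 10)
  expect_gte(mean(states == truth), 0.8)
})

test_that("bradykinesia threshold calibration is the condition midpoint", {
  expect_equal(calibrate_brady_threshold(c(0.3, 0.7), c("off", "on")), 0.5)
  expect_warning(
    th <- calibrate_brady_threshold(c(0.3, 0.6, 0.5, 0.7),
                                    c("off", "off", "on", "on")),
    "overlap")
  expect_equal(th, 0.525)
  expect_error(calibrate_brady_threshold(c(0.3, 0.4), c("off", "off")),
               "both conditions")
})

test_that("calibrated thresholds separate simulated patients per test", {
  # parameter-recovery: scripted effect sizes, held-out test classification
  cfg <- pipeline_config()
  prof <- cached_profile()
  mean_fl <- function(brady, seed) {
    ses <- simulate_session(protocol_script(list(
      activity_segment(if (brady) "brady_gait" else "gait", 40))),
      seed = seed)
    w <- run_pipeline(ses$stream, cfg, prof)$windows
    mean(w$fluidity[w$walking], na.rm = TRUE)
  }
  hits <- fps <- logical(6)
  for (p in 1:6) {
    s0 <- 5000 + 100 * p
    th <- calibrate_brady_threshold(
      c(mean_fl(TRUE, s0 + 1), mean_fl(FALSE, s0 + 2)), c("off", "on"))
    hits[p] <- mean_fl(TRUE, s0 + 3) < th
    fps[p] <- mean_fl(FALSE, s0 + 4) < th
  }
  expect_equal(mean(hits), 1)
  expect_gte(1 - mean(fps), 0.9)
})

test_that("the default dyskinesia tree fires on choreic, not resting windows", {
  cfg <- pipeline_config()
  dy <- simulate_session(protocol_script(list(
    activity_segment("dyskinetic", 60))), seed = 36)
  rs <- simulate_session(protocol_script(list(
    activity_segment("rest", 60))), seed = 37)
  flag_rate <- function(ses) {
    filt <- apply_filter(ses$stream, cfg$coeffs)$stream
    mean(vapply(segment_windows(filt, cfg$window), function(w)
      isTRUE(tree_eval(default_dysk_tree(),
                       extract_features(w, cfg$features))), logical(1)))
  }
  expect_gte(flag_rate(dy), 0.8)
  expect_lte(flag_rate(rs), 0.1)
})
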