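# Episodic evaluation and cohort summaries.
#
# An annotated symptom episode counts as detected when at least one
# positively flagged analysis window overlaps it (the matching rule is
# pluggable in principle; this default is the natural event-level reading).
# Specificity is window-based: among windows that overlap no episode at all,
# the fraction left unflagged.

COHORT_MD5 <- "48a2dee4cee45abb0b0048a5103a616e"

#' Validate an episode table
#'
#' @param episodes data.frame with `label`, `start_s`, `end_s`; episodes of
#'   one label must be non-overlapping and sorted.
#' @return the validated data.frame (class `episode_set`).
#' @export
episode_set <- function(episodes) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(episodes)))
  if (any(episodes$end_s <= episodes$start_s)) {
    stop("episodes must satisfy start < end", call. = FALSE)
  }
  for (lb in unique(episodes$label)) {
    e <- episodes[episodes$label == lb, , drop = FALSE]
    if (is.unsorted(e$start_s)) {
      stop("episodes must be sorted by start time within each label",
           call. = FALSE)
    }
    if (nrow(e) > 1L && any(e$start_s[-1] < e$end_s[-nrow(e)])) {
      stop("episodes of one label must not overlap", call. = FALSE)
    }
  }
  structure(episodes, class = c("episode_set", "data.frame"))
}

#' Episodic sensitivity and window specificity
#'
#' @param episodes ground-truth episode table (see [episode_set()]).
#' @param flags logical per-window detector output, window i starting at
#'   `t0 + (i-1) * stride`.
#' @param spec the [window_spec()] the flags were produced under.
#' @param t0 stream start time of window 1.
#' @param label if given, restrict the ground truth to this episode label.
#' @return an `eval_result`: `detected_episodes`, `total_episodes`,
#'   `sensitivity` (NA when there is no ground-truth episode),
#'   `flagged_negative_windows`, `total_negative_windows`, `specificity`.
#' @export
episodic_eval <- function(episodes, flags, spec = window_spec(), t0 = 0,
                          label = NULL) {
  if (!is.null(label)) episodes <- episodes[episodes$label == label, ,
                                            drop = FALSE]
  episodes <- episode_set(as.data.frame(episodes))
  nw <- length(flags)
  ws <- t0 + (seq_len(nw) - 1L) * spec$stride / spec$rate_hz
  we <- ws + spec$n / spec$rate_hz
  overlaps <- matrix(FALSE, nrow = nw, ncol = nrow(episodes))
  for (j in seq_len(nrow(episodes))) {
    overlaps[, j] <- ws < episodes$end_s[j] & we > episodes$start_s[j]
  }
  detected <- if (nrow(episodes) > 0L) {
    sum(vapply(seq_len(nrow(episodes)),
               function(j) any(flags & overlaps[, j]), logical(1)))
  } else 0L
  neg <- if (nrow(episodes) > 0L) !apply(overlaps, 1, any) else rep(TRUE, nw)
  structure(list(
    detected_episodes = detected, total_episodes = nrow(episodes),
    sensitivity = if (nrow(episodes) > 0L) detected / nrow(episodes)
    else NA_real_,
    flagged_negative_windows = sum(flags & neg),
    total_negative_windows = sum(neg),
    specificity = if (sum(neg) > 0L) 1 - sum(flags & neg) / sum(neg)
    else NA_real_), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> sensitivity %s (%d/%d episodes), specificity %s (%d/%d negative windows flagged)\n",
              if (is.na(x$sensitivity)) "NA"
              else sprintf("%.2f%%", 100 * x$sensitivity),
              x$detected_episodes, x$total_episodes,
              if (is.na(x$specificity)) "NA"
              else sprintf("%.2f%%", 100 * x$specificity),
              x$flagged_negative_windows, x$total_negative_windows))
  invisible(x)
}

#' Load the packaged patient-cohort baseline table
#'
#' Twelve patients with gender, Hoehn & Yahr stage in ON and OFF medication
#' state, age and UPDRS part III motor score in both states. The packaged
#' file is checksum-verified on load. Note the published prose swaps the
#' ON/OFF labels of the two UPDRS summary values relative to the printed
#' table; this table follows the printed column labels.
#'
#' @param path override the packaged fixture path (for testing).
#' @return `cohort_table` data.frame with 12 rows.
#' @export
cohort_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_baseline.csv", package = "pdwear")
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, COHORT_MD5)) {
    stop("cohort fixture checksum mismatch (file tampered or corrupted)",
         call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 12L) stop("cohort fixture must have 12 rows", call. = FALSE)
  structure(df, class = c("cohort_table", "data.frame"))
}

#' Per-column cohort summary statistics
#'
#' Mean and sample (n-1 denominator) standard deviation of each numeric
#' column — the dispersion convention behind the published "mean +/- sd"
#' figures, in contrast to the population moments used by the window
#' features.
#'
#' @param table a [cohort_table()].
#' @return data.frame with `column`, `mean`, `sd`.
#' @export
cohort_summary <- function(table = cohort_table()) {
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  num <- setdiff(num, "patient")
  data.frame(column = num,
             mean = vapply(num, function(cn) mean(table[[cn]]), numeric(1)),
             sd = vapply(num, function(cn) sd(table[[cn]]), numeric(1)),
             row.names = NULL)
}

#' Train gait and freezing-of-gait window classifiers on simulated sessions
#'
#' Builds a window-level training table from `n_sessions` freezing-protocol
#' sessions, plus bradykinetic-gait sessions (so the gait model learns both
#' normal and bradykinetic walking) and daily-living sessions with rest and
#' dyskinetic segments (so non-walking activity is represented), then fits
#' the two RBF-SVM classifiers.
#'
#' @param n_sessions simulated freezing-protocol sessions.
#' @param seed master seed.
#' @param config a [pipeline_config()].
#' @return list with `gait_model` and `fog_model` ([svm_model()]s).
#' @export
train_detectors <- function(n_sessions = 20L, seed = 1L,
                            config = pipeline_config()) {
  ts1 <- make_training_set(n_sessions, seed = seed, config = config)
  ts2 <- make_training_set(max(2L, n_sessions %/% 2L), seed = seed + 211L,
                           config = config,
                           protocol = list(brady = TRUE, fog_propensity = 0.3))
  daily <- protocol_script(list(
    activity_segment("rest", 30), activity_segment("gait", 15),
    activity_segment("dyskinetic", 20), activity_segment("rest", 15)))
  ts3 <- lapply(seq_len(max(2L, n_sessions %/% 4L)), function(s) {
    featurize_session(simulate_session(daily, fs = config$window$rate_hz,
                                       seed = seed * 1019L + s), config)
  })
  feats <- rbind(ts1$features, ts2$features,
                 do.call(rbind, lapply(ts3, `[[`, "features")))
  labels <- c(ts1$labels, ts2$labels,
              unlist(lapply(ts3, `[[`, "labels")))
  keep <- !is.na(labels)
  feats <- feats[keep, , drop = FALSE]; labels <- labels[keep]
  list(gait_model = fit_svm(feats, labels %in% c("gait", "brady_gait"),
                            seed = seed),
       fog_model = fit_svm(feats, labels == "fog", seed = seed + 1L))
}

#' End-to-end evaluation on held-out simulated sessions
#'
#' Trains the window classifiers on `n_train` seeded sessions, then (a)
#' evaluates freezing-of-gait detection episodically on `n_test` held-out
#' freezing-protocol sessions and (b) runs the per-test bradykinetic-gait
#' evaluation on `n_patients` simulated patients: per patient, calibration
#' sessions in both medication conditions fix the personal fluidity
#' threshold, and one held-out test per condition is then classified.
#'
#' @param n_train training sessions; `n_test` held-out freezing sessions.
#' @param n_test held-out test sessions.
#' @param n_patients simulated patients for the bradykinesia arm.
#' @param seed master seed; train and test session seeds are disjoint
#'   derivations of it.
#' @param config a [pipeline_config()].
#' @return list: `fog` ([episodic_eval()] result pooled over test sessions),
#'   `brady` (per-test `sensitivity`/`specificity`), `models`.
#' @export
end_to_end_eval <- function(n_train = 20L, n_test = 10L, n_patients = 20L,
                            seed = 7L, config = pipeline_config()) {
  models <- train_detectors(n_train, seed = seed, config = config)
  profile <- patient_profile(models$gait_model, models$fog_model)

  detected <- 0L; total <- 0L; fneg <- 0L; tneg <- 0L
  for (s in seq_len(n_test)) {
    sseed <- seed * 100003L + 7919L * s  # disjoint from training derivations
    script <- schaafsma_protocol(seed = sseed)
    ses <- simulate_session(script, fs = config$window$rate_hz, seed = sseed + 1L)
    res <- run_pipeline(ses$stream, config, profile)
    ev <- episodic_eval(ses$episodes, res$windows$fog, config$window,
                        label = "fog")
    detected <- detected + ev$detected_episodes
    total <- total + ev$total_episodes
    fneg <- fneg + ev$flagged_negative_windows
    tneg <- tneg + ev$total_negative_windows
  }
  fog <- structure(list(detected_episodes = detected, total_episodes = total,
                        sensitivity = if (total > 0) detected / total
                        else NA_real_,
                        flagged_negative_windows = fneg,
                        total_negative_windows = tneg,
                        specificity = 1 - fneg / tneg),
                   class = "eval_result")

  walk_script <- function(brady, amp, freq) {
    protocol_script(list(activity_segment("posture_transition", 2),
                         activity_segment(if (brady) "brady_gait" else "gait",
                                          40),
                         activity_segment("posture_transition", 2)),
                    effects = list(brady_amp = amp, brady_freq = freq))
  }
  mean_fluidity <- function(script, sseed) {
    ses <- simulate_session(script, fs = config$window$rate_hz, seed = sseed)
    res <- run_pipeline(ses$stream, config, profile)
    mean(res$windows$fluidity[res$windows$walking], na.rm = TRUE)
  }
  hits <- logical(n_patients); fps <- logical(n_patients)
  effects <- with_seed(seed + 31L,
                       data.frame(amp = runif(n_patients, 0.5, 0.7),
                                  freq = runif(n_patients, 0.5, 0.8)))
  for (pt in seq_len(n_patients)) {
    ps <- seed * 200003L + 104729L * pt
    calib_f <- c(mean_fluidity(walk_script(TRUE, effects$amp[pt],
                                           effects$freq[pt]), ps + 1L),
                 mean_fluidity(walk_script(TRUE, effects$amp[pt],
                                           effects$freq[pt]), ps + 2L),
                 mean_fluidity(walk_script(FALSE, 1, 1), ps + 3L),
                 mean_fluidity(walk_script(FALSE, 1, 1), ps + 4L))
    theta <- calibrate_brady_threshold(calib_f, c("off", "off", "on", "on"))
    hits[pt] <- mean_fluidity(walk_script(TRUE, effects$amp[pt],
                                          effects$freq[pt]), ps + 5L) < theta
    fps[pt] <- mean_fluidity(walk_script(FALSE, 1, 1), ps + 6L) < theta
  }
  list(fog = fog,
       brady = list(sensitivity = mean(hits), specificity = 1 - mean(fps),
                    n_patients = n_patients),
       models = models)
}
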