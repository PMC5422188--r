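# Symptom detectors at their temporal levels: gait and freezing of gait per
# window, bradykinetic gait and dyskinesia per minute, ON/OFF motor state
# per 10-minute block.
#
# Sign convention for fluidity: the score measures spectral concentration of
# gait energy, so LOWER values mean less fluid, more bradykinetic gait; a
# minute is flagged bradykinetic when its mean fluidity over gait windows
# falls BELOW the patient threshold theta_p.

#' Window-level gait detection
#'
#' @param fv named feature vector for the window.
#' @param model an [svm_model()], or a function `fv -> logical` (hook for
#'   custom or ground-truth-reading classifiers).
#' @return logical walking flag.
#' @export
detect_gait <- function(fv, model) {
  if (is.function(model)) return(isTRUE(model(fv)))
  svm_decision(model, fv)$label == 1
}

#' Window-level freezing-of-gait detection
#'
#' @inheritParams detect_gait
#' @return logical FoG flag.
#' @export
detect_fog <- function(fv, model) {
  if (is.function(model)) return(isTRUE(model(fv)))
  svm_decision(model, fv)$label == 1
}

locate_peak <- function(spec, band) {
  h <- band_harmonics(spec, band)
  if (length(h) == 0L) return(NULL)
  mag2 <- Mod(spec$values[h + 1L])^2
  hp <- h[which.max(mag2)]
  # quadratic interpolation on log-magnitude refines the peak below the DFT
  # bin width (0.3125 Hz at the default 128-sample, 40 Hz window)
  delta <- 0
  if (hp > 1L && hp < floor(spec$n / 2)) {
    m3 <- Mod(spec$values[hp + c(0L, 1L, 2L)])
    if (all(m3 > 0)) {
      lg <- log(m3)
      den <- lg[1] - 2 * lg[2] + lg[3]
      if (den < 0) delta <- max(-0.5, min(0.5, 0.5 * (lg[1] - lg[3]) / den))
    }
  }
  list(h = hp, energy = max(mag2),
       freq = (hp + delta) * spec$rate_hz / spec$n)
}

#' Gait fluidity score of a walking window
#'
#' Energy within `half_band_hz` of the dominant locomotor harmonic, as a
#' fraction of total non-DC power: near 1 for clean single-harmonic gait,
#' small for spectrally diffuse (non-fluid) movement. A window with zero
#' total power scores 0.
#'
#' @param window a `window` from [segment_windows()].
#' @param spectrum optional precomputed [stft()] of the vertical axis.
#' @param axis vertical axis name (default `"x"`).
#' @param locomotor locomotor [band_spec()] searched for the dominant peak.
#' @param half_band_hz half-width of the band kept around the peak.
#' @return fluidity score between 0 and 1.
#' @export
fluidity_score <- function(window, spectrum = NULL, axis = "x",
                           locomotor = band_spec(0.68, 3),
                           half_band_hz = 0.5) {
  if (is.null(spectrum)) spectrum <- stft(window[[axis]], window$rate_hz)
  tot <- total_nondc_power(spectrum)
  if (tot == 0) return(0)
  pk <- locate_peak(spectrum, locomotor)
  if (is.null(pk)) return(0)
  nyq <- spectrum$rate_hz / 2
  around <- band_spec(max(0, pk$freq - half_band_hz),
                      min(nyq, pk$freq + half_band_hz))
  band_energy(spectrum, around) / tot
}

#' Cadence and amplitude-based gait surrogates for one walking window
#'
#' The dominant locomotor-band harmonic of the waist vertical axis sits at
#' the step frequency (the trunk oscillates vertically once per step, twice
#' per stride cycle), so cadence = 60 * peak frequency in steps/min. The
#' peak must carry at least `min_fraction` of total non-DC power, otherwise
#' cadence is undefined (`NA`) for the window. Step length and velocity are
#' simple inverted-pendulum surrogates from the peak amplitude, reported for
#' completeness and excluded from any accuracy claim.
#'
#' @param spectrum a [stft()] of the vertical axis.
#' @param locomotor locomotor [band_spec()].
#' @param min_fraction minimum peak share of total non-DC power.
#' @param leg_m pendulum leg length in metres for the surrogates.
#' @return list: `cadence` (steps/min or NA), `step_length` (m),
#'   `step_velocity` (m/s); surrogates NA whenever cadence is.
#' @export
cadence_estimate <- function(spectrum, locomotor = band_spec(0.68, 3),
                             min_fraction = 0.1, leg_m = 0.9) {
  pk <- locate_peak(spectrum, locomotor)
  tot <- total_nondc_power(spectrum)
  if (is.null(pk) || tot == 0 || pk$energy / tot < min_fraction) {
    return(list(cadence = NA_real_, step_length = NA_real_,
                step_velocity = NA_real_))
  }
  cadence <- 60 * pk$freq
  amp_g <- 2 * sqrt(pk$energy) / spectrum$n        # sinusoid amplitude in G
  disp <- amp_g * 9.81 / (2 * pi * pk$freq)^2      # vertical excursion, m
  disp <- min(disp, leg_m)
  step_len <- 2 * sqrt(pmax(0, 2 * leg_m * disp - disp^2))
  list(cadence = cadence, step_length = step_len,
       step_velocity = step_len * cadence / 60)
}

#' Default per-minute quorum configuration
#'
#' `q_gait` gait windows are required before a minute is evaluated at all;
#' a minute is dyskinetic when at least `q_dysk_frac` of its non-gait
#' windows carry the dyskinesia label.
#'
#' @return list of quorum defaults.
#' @export
default_quorum <- function() list(q_gait = 10L, q_dysk_frac = 0.5)

#' Aggregate one minute of window decisions
#'
#' @param decisions data.frame of window decisions for one minute with
#'   columns `walking`, `fog`, `fluidity`, `dysk`, `cadence`,
#'   `step_length`, `step_velocity` (typically 37 rows at the 1.6 s stride).
#' @param profile a [patient_profile()] supplying `theta_p`.
#' @param quorum quorum configuration, see [default_quorum()].
#' @param minute 0-based minute index recorded in the output.
#' @return a `minute_output`: `valid` (gait quorum met), `brady` flag and
#'   `brady_score` (mean fluidity over gait windows), `dysk` flag, median
#'   `cadence` and surrogate medians; symptom fields are `NA` when the
#'   quorum fails.
#' @export
minute_aggregate <- function(decisions, profile, quorum = default_quorum(),
                             minute = 0L) {
  n <- if (is.null(decisions)) 0L else nrow(decisions)
  n_gait <- if (n > 0L) sum(decisions$walking) else 0L
  valid <- n_gait >= quorum$q_gait
  out <- list(minute = minute, valid = valid, n_windows = n, n_gait = n_gait,
              brady = NA, brady_score = NA_real_, dysk = NA,
              cadence = NA_real_, step_length = NA_real_,
              step_velocity = NA_real_)
  if (valid) {
    g <- decisions[decisions$walking, , drop = FALSE]
    out$brady_score <- mean(g$fluidity, na.rm = TRUE)
    out$brady <- is.finite(profile$theta_p) && out$brady_score < profile$theta_p
    ng <- decisions[!decisions$walking, , drop = FALSE]
    out$dysk <- nrow(ng) > 0L &&
      sum(ng$dysk) >= quorum$q_dysk_frac * nrow(ng)
    out$cadence <- median(g$cadence, na.rm = TRUE)
    out$step_length <- median(g$step_length, na.rm = TRUE)
    out$step_velocity <- median(g$step_velocity, na.rm = TRUE)
  }
  structure(out, class = "minute_output")
}

#' Default ON/OFF decision thresholds
#'
#' @return list: `brady_off` (bradykinetic-minute fraction at or above which
#'   the block is OFF), `dysk_on` (dyskinetic fraction at or above which it
#'   is ON), `brady_on` (bradykinetic fraction at or below which it is ON).
#' @export
default_onoff_thresholds <- function() {
  list(brady_off = 0.5, dysk_on = 0.2, brady_on = 0.2)
}

#' Motor state of one 10-minute block
#'
#' A small fixed decision rule over the block's valid minutes: OFF when at
#' least half are bradykinetic and fewer than 20% dyskinetic; ON when at
#' least 20% are dyskinetic or at most 20% bradykinetic; otherwise (or with
#' no valid minute) undetermined. Freezing-of-gait output never enters this
#' decision.
#'
#' @param minutes list of [minute_aggregate()] outputs (one block, usually 10).
#' @param thresholds see [default_onoff_thresholds()].
#' @param block 0-based block index recorded in the output.
#' @return a `tenmin_output` with `state` in `"ON"`, `"OFF"`,
#'   `"undetermined"`.
#' @export
onoff_state <- function(minutes, thresholds = default_onoff_thresholds(),
                        block = 0L) {
  valid <- Filter(function(m) isTRUE(m$valid), minutes)
  state <- "undetermined"
  if (length(valid) > 0L) {
    bf <- mean(vapply(valid, function(m) isTRUE(m$brady), logical(1)))
    df <- mean(vapply(valid, function(m) isTRUE(m$dysk), logical(1)))
    if (bf >= thresholds$brady_off && df < thresholds$dysk_on) state <- "OFF"
    else if (df >= thresholds$dysk_on || bf <= thresholds$brady_on) state <- "ON"
  }
  structure(list(block = block, state = state, n_valid = length(valid)),
            class = "tenmin_output")
}

#' Calibrate the patient bradykinesia threshold
#'
#' Midpoint of the two condition means of per-test mean fluidity (a simple
#' pluggable surrogate for regression-based personalisation): tests scoring
#' below the returned threshold are classified bradykinetic. Always returns
#' a threshold; emits a warning when the two conditions' score ranges
#' overlap (not separable).
#'
#' @param fluidity numeric per-test mean fluidity scores.
#' @param condition parallel 2-level factor/character: which medication
#'   condition each test belongs to. The lower-scoring condition is taken as
#'   the bradykinetic one.
#' @return scalar threshold `theta_p`.
#' @export
calibrate_brady_threshold <- function(fluidity, condition) {
  condition <- as.factor(as.character(condition))
  if (nlevels(condition) < 2L) {
    stop("calibration requires tests from both conditions", call. = FALSE)
  }
  if (nlevels(condition) > 2L) {
    stop("calibration expects exactly two conditions", call. = FALSE)
  }
  means <- tapply(fluidity, condition, mean)
  lo <- names(means)[which.min(means)]
  hi <- names(means)[which.max(means)]
  if (max(fluidity[condition == lo]) >= min(fluidity[condition == hi])) {
    warning("calibration conditions overlap; threshold may not separate them",
            call. = FALSE)
  }
  unname(mean(means))
}

#' Default dyskinesia window classifier
#'
#' A depth-2 decision tree over spectral features, calibrated on the
#' synthetic-data generator (the deployed tree is not published): a window
#' is dyskinetic when its vertical dyskinetic-band (1, 4] Hz energy is high
#' while freeze-band energy stays moderate. Applied to non-gait windows only
#' by [minute_aggregate()].
#'
#' @param e_dysk_min minimum vertical dyskinetic-band energy.
#' @param e_freeze_max maximum vertical freeze-band energy.
#' @return a decision tree for [tree_eval()] returning TRUE/FALSE.
#' @export
default_dysk_tree <- function(e_dysk_min = 50, e_freeze_max = 100) {
  tree_node("E_dyskinetic_x", e_dysk_min,
            tree_leaf(FALSE),
            tree_node("E_freeze_x", e_freeze_max,
                      tree_leaf(TRUE), tree_leaf(FALSE)))
}

#' Bundle the per-patient models and threshold
#'
#' @param gait_model walking classifier ([svm_model()] or function hook).
#' @param fog_model freezing-of-gait classifier (ditto).
#' @param theta_p bradykinesia fluidity threshold from
#'   [calibrate_brady_threshold()]; `NA` disables the bradykinesia flag.
#' @param dysk_tree dyskinesia window classifier for [tree_eval()].
#' @return a `patient_profile`.
#' @export
patient_profile <- function(gait_model, fog_model, theta_p = NA_real_,
                            dysk_tree = default_dysk_tree()) {
  structure(list(gait_model = gait_model, fog_model = fog_model,
                 theta_p = theta_p, dysk_tree = dysk_tree),
            class = "patient_profile")
}
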