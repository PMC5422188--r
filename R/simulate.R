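# Seeded generator of labelled waist-accelerometry sessions.
#
# Signal model (vertical axis x, in G): gravity 1 G plus, during gait, three
# harmonics of the step frequency (the trunk bounces once per step) plus
# white noise. Freezing episodes attenuate the locomotor harmonics to 20%
# and add a trembling component drawn from the 3-8 Hz freeze band;
# bradykinetic gait scales step frequency and amplitude down by patient
# effect factors; posture transitions smoothly reorient gravity over the
# segment; dyskinetic segments superpose irregular low-frequency (1-3 Hz)
# choreic oscillations. Horizontal axes carry scaled copies with independent
# phases. All randomness flows from the session seed.

SIM_LABELS <- c("rest", "gait", "brady_gait", "fog", "dyskinetic",
                "posture_transition")

#' Simulator signal defaults
#'
#' Amplitudes in G; frequencies in Hz. `step_freq` 1.9 Hz with harmonic
#' amplitudes 0.35/0.15/0.05 G gives a vertical gait standard deviation of
#' about 0.27 G, typical of waist-worn recordings; freezing attenuates the
#' locomotor harmonics by `fog_loco_atten` and adds a `fog_tremble_amp`
#' component at a frequency drawn from the freeze band.
#'
#' @return named list of defaults, all overridable per segment.
#' @export
sim_defaults <- function() {
  list(step_freq = 1.9, harmonic_amps = c(0.35, 0.15, 0.05),
       horiz_factors = c(y = 0.45, z = 0.3), noise_sd = 0.03,
       fog_loco_atten = 0.2, fog_tremble_amp = 0.25,
       fog_band = c(3, 8), dysk_amp = 0.2, dysk_freq_range = c(1, 3),
       transition_angle = 0.4, brady_am_depth = 0.6, brady_noise_sd = 0.06)
}

#' Describe one scripted activity segment
#'
#' @param label one of `rest`, `gait`, `brady_gait`, `fog`, `dyskinetic`,
#'   `posture_transition`.
#' @param duration_s segment duration, > 0.
#' @param params per-segment overrides of [sim_defaults()] entries.
#' @return an `activity_segment`.
#' @export
activity_segment <- function(label, duration_s, params = list()) {
  if (!label %in% SIM_LABELS) {
    stop("unsupported segment label: ", label, call. = FALSE)
  }
  stopifnot(duration_s > 0)
  structure(list(label = label, duration_s = duration_s, params = params),
            class = "activity_segment")
}

#' Assemble an ordered protocol script
#'
#' @param segments list of [activity_segment()]s.
#' @param effects patient effect parameters: `brady_amp` and `brady_freq`
#'   multiply gait amplitude and step frequency in `brady_gait` segments;
#'   `fog_propensity` records the scripted freezing propensity.
#' @return a `protocol_script`.
#' @export
protocol_script <- function(segments,
                            effects = list(brady_amp = 0.6, brady_freq = 0.6,
                                           fog_propensity = 0)) {
  stopifnot(length(segments) > 0L,
            all(vapply(segments, inherits, TRUE, "activity_segment")))
  structure(list(segments = segments, effects = effects),
            class = "protocol_script")
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

gait_harmonics <- function(t, f, amps, phases) {
  out <- numeric(length(t))
  for (k in seq_along(amps)) {
    out <- out + amps[k] * sin(2 * pi * k * f * t + phases[k])
  }
  out
}

synth_segment <- function(seg, fs, p) {
  p <- modifyList(p, seg$params)
  n <- max(1L, round(seg$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  noise <- function() rnorm(n, sd = p$noise_sd)
  x <- y <- z <- numeric(n)
  ph <- function() runif(3, 0, 2 * pi)
  switch(seg$label,
    rest = {
      x <- 1 + noise(); y <- noise(); z <- noise()
    },
    gait = ,
    brady_gait = {
      f <- p$step_freq; amps <- p$harmonic_amps
      am <- 1
      if (seg$label == "brady_gait") {
        # bradykinetic gait: slower, smaller, and crucially less rhythmic --
        # slow amplitude modulation plus extra broadband noise spread the
        # locomotor peak, which is what the fluidity score picks up
        f <- f * p$brady_freq; amps <- amps * p$brady_amp
        am <- 1 + p$brady_am_depth *
          sin(2 * pi * runif(1, 0.5, 0.9) * t + runif(1, 0, 2 * pi))
        p$noise_sd <- p$brady_noise_sd
      }
      x <- 1 + am * gait_harmonics(t, f, amps, ph()) + noise()
      y <- am * gait_harmonics(t, f, amps * p$horiz_factors["y"], ph()) +
        noise()
      z <- am * gait_harmonics(t, f, amps * p$horiz_factors["z"], ph()) +
        noise()
    },
    fog = {
      f <- p$step_freq
      amps <- p$harmonic_amps * p$fog_loco_atten
      f_fr <- runif(1, p$fog_band[1], p$fog_band[2])
      phf <- runif(3, 0, 2 * pi)
      x <- 1 + gait_harmonics(t, f, amps, ph()) +
        p$fog_tremble_amp * sin(2 * pi * f_fr * t + phf[1]) + noise()
      y <- gait_harmonics(t, f, amps * p$horiz_factors["y"], ph()) +
        0.6 * p$fog_tremble_amp * sin(2 * pi * f_fr * t + phf[2]) + noise()
      z <- gait_harmonics(t, f, amps * p$horiz_factors["z"], ph()) +
        0.4 * p$fog_tremble_amp * sin(2 * pi * f_fr * t + phf[3]) + noise()
    },
    dyskinetic = {
      fd <- runif(2, p$dysk_freq_range[1], p$dysk_freq_range[2])
      phd <- runif(2, 0, 2 * pi)
      osc <- p$dysk_amp * (sin(2 * pi * fd[1] * t + phd[1]) +
                             sin(2 * pi * fd[2] * t + phd[2]))
      x <- 1 + osc + noise(); y <- 0.7 * osc + noise(); z <- 0.7 * osc + noise()
    },
    posture_transition = {
      th <- p$transition_angle * smoothstep(t / seg$duration_s)
      x <- cos(th) + noise(); y <- sin(th) + noise(); z <- noise()
    })
  list(x = x, y = y, z = z)
}

#' Synthesise one labelled accelerometry session
#'
#' Deterministic given `(script, fs, seed)`; the ground-truth episode table
#' partitions the timeline and each episode's span carries its segment's
#' signal regime.
#'
#' @param script a [protocol_script()].
#' @param fs sampling rate, 40 (processing) or 50 (capture) Hz by default.
#' @param seed session seed.
#' @return a `labelled_session`: `stream` ([signal_stream()]), `episodes`
#'   data.frame (`label`, `start_s`, `end_s`), `fs`, `seed`.
#' @export
simulate_session <- function(script, fs = 40, seed = 1L) {
  if (!fs %in% c(40, 50)) {
    warning("simulator is tuned for 40 or 50 Hz sampling", call. = FALSE)
  }
  p <- sim_defaults()
  if (!is.null(script$effects$brady_amp)) p$brady_amp <- script$effects$brady_amp
  if (!is.null(script$effects$brady_freq)) p$brady_freq <- script$effects$brady_freq
  if (is.null(p$brady_amp)) p$brady_amp <- 0.6
  if (is.null(p$brady_freq)) p$brady_freq <- 0.6
  with_seed(seed, {
    xs <- ys <- zs <- list()
    eps <- list()
    t_cursor <- 0
    for (i in seq_along(script$segments)) {
      seg <- script$segments[[i]]
      sig <- synth_segment(seg, fs, p)
      xs[[i]] <- sig$x; ys[[i]] <- sig$y; zs[[i]] <- sig$z
      dur <- length(sig$x) / fs
      eps[[i]] <- data.frame(label = seg$label, start_s = t_cursor,
                             end_s = t_cursor + dur)
      t_cursor <- t_cursor + dur
    }
    structure(list(stream = signal_stream(unlist(xs), unlist(ys), unlist(zs),
                                          rate_hz = fs),
                   episodes = do.call(rbind, eps), fs = fs, seed = seed),
              class = "labelled_session")
  })
}

#' @export
print.labelled_session <- function(x, ...) {
  cat(sprintf("<labelled_session> %.1f s @ %g Hz, %d segments, seed %s\n",
              stream_length(x$stream) / x$fs, x$fs, nrow(x$episodes),
              format(x$seed)))
  print(table(x$episodes$label))
  invisible(x)
}

#' Freezing-elicitation protocol script
#'
#' Stand-up transition, a 20 m walk, turns in both directions, a
#' narrow-space passage (the highest freezing propensity) and a sit-down
#' transition — the situations in which freezing is typically elicited.
#' Freezing episodes are inserted stochastically: with probability
#' `fog_propensity` in the narrow-space passage and half that in each turn,
#' splitting the segment around a 3-6 s freeze.
#'
#' @param params overrides: `fog_propensity` (default 0.6), `walk_speed_m_s`
#'   (1), `walk_distance_m` (20), `turn_s` (5), `narrow_s` (10),
#'   `transition_s` (2), `brady` (logical; gait segments become
#'   `brady_gait`), `brady_amp`, `brady_freq` effect factors.
#' @param seed seed governing symptom insertion.
#' @return a [protocol_script()].
#' @export
schaafsma_protocol <- function(params = list(), seed = 1L) {
  p <- modifyList(list(fog_propensity = 0.6, walk_speed_m_s = 1,
                       walk_distance_m = 20, turn_s = 5, narrow_s = 10,
                       transition_s = 2, brady = FALSE, brady_amp = 0.6,
                       brady_freq = 0.6), params)
  gait_label <- if (isTRUE(p$brady)) "brady_gait" else "gait"
  walk_s <- p$walk_distance_m / p$walk_speed_m_s
  with_seed(seed, {
    risky <- function(duration, propensity) {
      # a gait segment that may be interrupted by one freeze episode
      if (runif(1) < propensity) {
        pre <- duration * runif(1, 0.2, 0.5)
        fog <- runif(1, 3, 6)
        list(activity_segment(gait_label, pre),
             activity_segment("fog", fog),
             activity_segment(gait_label, max(1, duration - pre)))
      } else {
        list(activity_segment(gait_label, duration))
      }
    }
    segs <- c(list(activity_segment("posture_transition", p$transition_s)),
              list(activity_segment(gait_label, walk_s)),
              risky(p$turn_s, p$fog_propensity * 0.5),
              risky(p$turn_s, p$fog_propensity * 0.5),
              risky(p$narrow_s, p$fog_propensity),
              list(activity_segment("posture_transition", p$transition_s)))
    protocol_script(segs, effects = list(brady_amp = p$brady_amp,
                                         brady_freq = p$brady_freq,
                                         fog_propensity = p$fog_propensity))
  })
}

window_gt_label <- function(start_s, end_s, episodes) {
  ov <- pmin(end_s, episodes$end_s) - pmax(start_s, episodes$start_s)
  if (all(ov <= 0)) return(NA_character_)
  as.character(episodes$label[which.max(ov)])
}

#' Featurise a labelled session into windows with ground-truth labels
#'
#' Filters, windows and featurises the session exactly as the pipeline does;
#' each window takes the episode label covering the majority of its span.
#'
#' @param session a `labelled_session`.
#' @param config a [pipeline_config()].
#' @return list with `features` (matrix), `labels` (character), `start`.
#' @export
featurize_session <- function(session, config = pipeline_config()) {
  filtered <- apply_filter(session$stream, config$coeffs)$stream
  wins <- segment_windows(filtered, config$window)
  if (length(wins) == 0L) {
    return(list(features = NULL, labels = character(0), start = integer(0)))
  }
  fm <- t(vapply(wins, extract_features, config = config$features,
                 numeric(length(config$features$names))))
  lb <- vapply(wins, function(w) {
    window_gt_label(w$start / session$fs,
                    (w$start + config$window$n) / session$fs,
                    session$episodes)
  }, "")
  list(features = fm, labels = lb,
       start = vapply(wins, `[[`, integer(1), "start"))
}

#' Build a labelled window-level training table from simulated sessions
#'
#' Each session is filtered, windowed and featurised exactly as by the
#' pipeline; a window takes the ground-truth label covering the majority of
#' its span.
#'
#' @param n_sessions number of sessions (>= 2).
#' @param seed master seed; per-session seeds are derived from it.
#' @param config a [pipeline_config()].
#' @param protocol parameter overrides passed to [schaafsma_protocol()].
#' @return list: `features` (matrix, one row per window), `labels`
#'   (character ground-truth label per window), `session`, `start`.
#' @export
make_training_set <- function(n_sessions, seed = 1L,
                              config = pipeline_config(), protocol = list()) {
  stopifnot(n_sessions >= 2L)
  feats <- list(); labs <- list(); sess <- list(); starts <- list()
  for (s in seq_len(n_sessions)) {
    script <- schaafsma_protocol(protocol, seed = seed * 1009L + s)
    ses <- simulate_session(script, fs = config$window$rate_hz,
                            seed = seed * 1013L + s)
    fz <- featurize_session(ses, config)
    if (is.null(fz$features)) next
    feats[[s]] <- fz$features; labs[[s]] <- fz$labels
    sess[[s]] <- rep(s, length(fz$labels))
    starts[[s]] <- fz$start
  }
  labels <- unlist(labs)
  if (length(unique(labels)) < 2L) {
    warning("training table is single-class", call. = FALSE)
  }
  list(features = do.call(rbind, feats), labels = labels,
       session = unlist(sess), start = unlist(starts))
}

#' Convert a simulated session to acquisition frames
#'
#' The acceleration stream fills the primary accelerometer channels
#' (quantised to the single-precision storage format); gyroscope,
#' magnetometer, barometer and temperature channels are zero-filled; clock
#' registers advance from `start_time`.
#'
#' @param session a `labelled_session`.
#' @param start_time POSIXct session start (default a fixed epoch).
#' @return list of [sample_frame()]s.
#' @export
session_to_frames <- function(session,
                              start_time = as.POSIXct("2026-01-01 08:00:00",
                                                      tz = "UTC")) {
  n <- stream_length(session$stream)
  ax <- lapply(session$stream$axes, float32)
  lapply(seq_len(n), function(i) {
    tt <- as.POSIXlt(start_time + (i - 1L) %/% session$fs)
    sample_frame(acc1 = c(ax$x[i], ax$y[i], ax$z[i]),
                 rtc = c(tt$year + 1900, tt$mon + 1, tt$mday, tt$hour,
                         tt$min, floor(tt$sec)),
                 counter = i - 1L)
  })
}

#' Rebuild a signal stream from acquisition frames
#'
#' @param frames list of [sample_frame()]s.
#' @param rate_hz sampling rate of the recording.
#' @param t0 stream start time in seconds.
#' @return a [signal_stream()] from the primary accelerometer channels.
#' @export
frames_to_stream <- function(frames, rate_hz, t0 = 0) {
  m <- vapply(frames, `[[`, numeric(3), "acc1")
  signal_stream(m[1, ], m[2, ], m[3, ], rate_hz = rate_hz, t0 = t0)
}
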