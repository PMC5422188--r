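# Multi-rate orchestration: samples (40 Hz) -> windows (every 1.6 s) ->
# minutes -> 10-minute blocks, with an event log.
#
# Batch and streaming execution share one window-level processor, and the
# filter recursion carries its state across chunks, so feeding a stream one
# sample at a time yields outputs bit-identical to whole-stream processing.
# Minute m covers windows whose start sample falls in [m*60*rate,
# (m+1)*60*rate); a minute is emitted once the stream has passed its end.
# Timestamps are stream time (t0 + sample/rate); a freezing episode's events
# span [first flagged window start, last flagged window start + stride].

#' Pipeline configuration
#'
#' @param window a [window_spec()] (sets the processing rate).
#' @param cutoff_hz low-pass cutoff in Hz. The deployed 2nd-order Butterworth
#'   stage does not publish its cutoff; the 15 Hz default preserves the
#'   movement band of interest (up to 20 Hz) while attenuating near-Nyquist
#'   noise.
#' @param features a [feature_config()].
#' @param quorum per-minute quorums, see [default_quorum()].
#' @param onoff ON/OFF thresholds, see [default_onoff_thresholds()].
#' @param fluidity_half_band_hz half-band for [fluidity_score()].
#' @param vertical_axis stream axis carrying gravity.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(window = window_spec(), cutoff_hz = 15,
                            features = feature_config(),
                            quorum = default_quorum(),
                            onoff = default_onoff_thresholds(),
                            fluidity_half_band_hz = 0.5,
                            vertical_axis = "x") {
  coeffs <- design_lowpass(cutoff_hz, window$rate_hz)  # validates cutoff
  structure(list(window = window, cutoff_hz = cutoff_hz, coeffs = coeffs,
                 features = features, quorum = quorum, onoff = onoff,
                 fluidity_half_band_hz = fluidity_half_band_hz,
                 vertical_axis = vertical_axis),
            class = "pipeline_config")
}

empty_events <- function() {
  data.frame(time_s = numeric(0), level = character(0), kind = character(0),
             payload = character(0), stringsAsFactors = FALSE)
}

event_row <- function(time_s, level, kind, payload = "") {
  data.frame(time_s = time_s, level = level, kind = kind, payload = payload,
             stringsAsFactors = FALSE)
}

decision_row <- function(index, start, time_s, walking, fog, fluidity, dysk,
                         cad) {
  data.frame(window = index, start = start, time_s = time_s,
             walking = walking, fog = fog, fluidity = fluidity, dysk = dysk,
             cadence = cad$cadence, step_length = cad$step_length,
             step_velocity = cad$step_velocity)
}

proc_init <- function(config, profile, rate_hz, t0) {
  if (rate_hz != config$window$rate_hz) {
    stop(sprintf("stream rate %g Hz does not match the configured %g Hz; no resampling is performed",
                 rate_hz, config$window$rate_hz), call. = FALSE)
  }
  list(config = config, profile = profile, rate = rate_hz, t0 = t0,
       n = config$window$n, stride = config$window$stride,
       windex = 0L, next_minute = 0L,
       decisions = list(), minutes = list(), block_buffer = list(),
       tenmin = list(), events = list(),
       in_fog = FALSE, last_fog_start = NA_real_)
}

proc_emit <- function(state, ev) {
  state$events[[length(state$events) + 1L]] <- ev
  state
}

# Aggregate and emit minute `state$next_minute` from the stored decisions.
proc_flush_minute <- function(state) {
  m <- state$next_minute
  spm <- 60 * state$rate
  rows <- Filter(function(d) d$start >= m * spm && d$start < (m + 1) * spm,
                 state$decisions)
  df <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  mo <- minute_aggregate(df, state$profile, state$config$quorum, minute = m)
  state$minutes[[length(state$minutes) + 1L]] <- mo
  tb <- state$t0 + (m + 1) * 60
  if (isTRUE(mo$brady)) {
    state <- proc_emit(state, event_row(tb, "minute", "BRADY_MINUTE",
                                        sprintf("score=%.4f", mo$brady_score)))
  }
  if (isTRUE(mo$dysk)) {
    state <- proc_emit(state, event_row(tb, "minute", "DYSK_MINUTE"))
  }
  state$block_buffer[[length(state$block_buffer) + 1L]] <- mo
  if (length(state$block_buffer) == 10L) {
    b <- length(state$tenmin)
    to <- onoff_state(state$block_buffer, state$config$onoff, block = b)
    state$tenmin[[b + 1L]] <- to
    state$block_buffer <- list()
    if (to$state %in% c("ON", "OFF")) {
      state <- proc_emit(state, event_row(state$t0 + (b + 1) * 600, "tenmin",
                                          to$state))
    }
  }
  state$next_minute <- m + 1L
  state
}

proc_window <- function(state, xb, yb, zb, start) {
  spm <- 60 * state$rate
  while (start >= (state$next_minute + 1L) * spm) {
    state <- proc_flush_minute(state)
  }
  state$windex <- state$windex + 1L
  w <- structure(list(index = state$windex, start = start, x = xb, y = yb,
                      z = zb, rate_hz = state$rate), class = "window")
  fv <- extract_features(w, state$config$features)
  # window span attributes let function-hook classifiers (e.g. ground-truth
  # reading stubs in plumbing tests) locate the window in stream time
  attr(fv, "start_s") <- state$t0 + start / state$rate
  attr(fv, "end_s") <- state$t0 + (start + state$n) / state$rate
  walking <- detect_gait(fv, state$profile$gait_model)
  fog <- detect_fog(fv, state$profile$fog_model)
  vspec <- stft(w[[state$config$vertical_axis]], state$rate)
  fl <- if (walking) {
    fluidity_score(w, vspec, axis = state$config$vertical_axis,
                   half_band_hz = state$config$fluidity_half_band_hz)
  } else NA_real_
  dysk <- isTRUE(tree_eval(state$profile$dysk_tree, fv))
  cad <- if (walking) cadence_estimate(vspec) else {
    list(cadence = NA_real_, step_length = NA_real_, step_velocity = NA_real_)
  }
  tw <- state$t0 + start / state$rate
  if (fog && !state$in_fog) {
    state <- proc_emit(state, event_row(tw, "window", "FOG_START"))
    state$in_fog <- TRUE
  } else if (!fog && state$in_fog) {
    state <- proc_emit(state, event_row(tw, "window", "FOG_END"))
    state$in_fog <- FALSE
  }
  if (fog) state$last_fog_start <- start
  state$decisions[[length(state$decisions) + 1L]] <-
    decision_row(state$windex, start, tw, walking, fog, fl, dysk, cad)
  state
}

proc_finish <- function(state, total_count) {
  pre <- length(state$events)
  if (state$in_fog) {
    state <- proc_emit(state, event_row(
      state$t0 + (state$last_fog_start + state$stride) / state$rate,
      "window", "FOG_END"))
    state$in_fog <- FALSE
  }
  spm <- 60 * state$rate
  while (total_count >= (state$next_minute + 1L) * spm) {
    state <- proc_flush_minute(state)
  }
  if (length(state$events) > pre) {  # keep the tail timestamp-sorted
    tail_ev <- state$events[(pre + 1L):length(state$events)]
    ord <- order(vapply(tail_ev, function(e) e$time_s, numeric(1)))
    state$events <- c(state$events[seq_len(pre)], tail_ev[ord])
  }
  state
}

proc_results <- function(state) {
  minutes_df <- if (length(state$minutes) > 0L) {
    do.call(rbind, lapply(state$minutes, function(m)
      data.frame(minute = m$minute, valid = m$valid, n_windows = m$n_windows,
                 n_gait = m$n_gait, brady = m$brady,
                 brady_score = m$brady_score, dysk = m$dysk,
                 cadence = m$cadence, step_length = m$step_length,
                 step_velocity = m$step_velocity)))
  } else {
    data.frame(minute = integer(0), valid = logical(0), n_windows = integer(0),
               n_gait = integer(0), brady = logical(0),
               brady_score = numeric(0), dysk = logical(0),
               cadence = numeric(0), step_length = numeric(0),
               step_velocity = numeric(0))
  }
  tenmin_df <- if (length(state$tenmin) > 0L) {
    do.call(rbind, lapply(state$tenmin, function(b)
      data.frame(block = b$block, state = b$state, n_valid = b$n_valid)))
  } else {
    data.frame(block = integer(0), state = character(0), n_valid = integer(0))
  }
  windows_df <- if (length(state$decisions) > 0L) {
    do.call(rbind, state$decisions)
  } else {
    decision_row(integer(0), integer(0), numeric(0), logical(0), logical(0),
                 numeric(0), logical(0),
                 list(cadence = numeric(0), step_length = numeric(0),
                      step_velocity = numeric(0)))
  }
  events_df <- if (length(state$events) > 0L) do.call(rbind, state$events)
  else empty_events()
  out <- list(windows = windows_df, minutes = minutes_df, tenmin = tenmin_df,
              events = events_df)
  out <- lapply(out, function(df) { rownames(df) <- NULL; df })
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d windows, %d minutes, %d 10-min blocks, %d events\n",
              nrow(x$windows), nrow(x$minutes), nrow(x$tenmin),
              nrow(x$events)))
  if (nrow(x$events) > 0L) {
    tab <- table(x$events$kind)
    cat("  events:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Run the full detection pipeline over a stream
#'
#' Filters, windows, classifies and aggregates one session in a single call;
#' equivalent, output for output, to feeding the stream through
#' [stream_step()].
#'
#' @param stream a [signal_stream()] at the configured rate.
#' @param config a [pipeline_config()].
#' @param profile a [patient_profile()].
#' @return a `pipeline_result`: data.frames `windows`, `minutes`, `tenmin`
#'   and the `events` log.
#' @export
run_pipeline <- function(stream, config = pipeline_config(), profile) {
  state <- proc_init(config, profile, stream$rate_hz, stream$t0)
  filtered <- apply_filter(stream, config$coeffs)$stream
  for (w in segment_windows(filtered, config$window)) {
    state <- proc_window(state, w$x, w$y, w$z, w$start)
  }
  state <- proc_finish(state, stream_length(stream))
  proc_results(state)
}

#' Initialise per-sample streaming state
#'
#' @param config a [pipeline_config()].
#' @param profile a [patient_profile()].
#' @param rate_hz incoming sample rate (must match the configuration).
#' @param t0 stream start time in seconds.
#' @return an opaque, serialisable streaming state for [stream_step()].
#' @export
stream_init <- function(config = pipeline_config(), profile, rate_hz = NULL,
                        t0 = 0) {
  if (is.null(rate_hz)) rate_hz <- config$window$rate_hz
  st <- proc_init(config, profile, rate_hz, t0)
  st$filt_state <- NULL
  st$count <- 0L
  st$buf <- list(x = numeric(st$n), y = numeric(st$n), z = numeric(st$n))
  st
}

#' Feed one sample into the streaming pipeline
#'
#' The state is a plain serialisable value: a run can be checkpointed with
#' `serialize()` mid-session and resumed, reproducing the uninterrupted run
#' exactly.
#'
#' @param state state from [stream_init()] or a previous step.
#' @param sample length-3 numeric `c(x, y, z)` acceleration in G.
#' @return list with the updated `state` and an `events` data.frame holding
#'   any events this sample emitted.
#' @export
stream_step <- function(state, sample) {
  stopifnot(length(sample) == 3L)
  pre_ev <- length(state$events)
  mini <- signal_stream(sample[1], sample[2], sample[3], state$rate)
  f <- apply_filter(mini, state$config$coeffs, state$filt_state)
  state$filt_state <- f$state
  slot <- (state$count %% state$n) + 1L
  state$buf$x[slot] <- f$stream$axes$x
  state$buf$y[slot] <- f$stream$axes$y
  state$buf$z[slot] <- f$stream$axes$z
  state$count <- state$count + 1L
  if (state$count >= state$n &&
      (state$count - state$n) %% state$stride == 0L) {
    start <- state$count - state$n
    idx <- ((start + seq_len(state$n) - 1L) %% state$n) + 1L
    state <- proc_window(state, state$buf$x[idx], state$buf$y[idx],
                         state$buf$z[idx], start)
  }
  new_ev <- if (length(state$events) > pre_ev) {
    do.call(rbind, state$events[(pre_ev + 1L):length(state$events)])
  } else empty_events()
  list(state = state, events = new_ev)
}

#' Close a streaming run and collect its outputs
#'
#' Flushes the trailing freezing episode and any completed minutes, then
#' returns the same structure as [run_pipeline()].
#'
#' @param state state from [stream_step()].
#' @return a `pipeline_result`.
#' @export
stream_finish <- function(state) {
  state <- proc_finish(state, state$count)
  proc_results(state)
}
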