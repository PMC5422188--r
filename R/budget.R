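# Storage, model-memory and battery arithmetic.
#
# Megabytes and kilobytes are decimal (10^6 and 10^3 bytes) throughout:
# the convention under which a 128-byte frame at 50 Hz comes to 552.96 MB
# per day. Every result carries its formula string for auditability.

budget_result <- function(quantity, value, unit, formula) {
  structure(list(quantity = quantity, value = value, unit = unit,
                 formula = formula), class = "budget_result")
}

#' @export
print.budget_result <- function(x, ...) {
  cat(sprintf("%s: %s %s   [%s]\n", x$quantity, format(x$value), x$unit,
              x$formula))
  invisible(x)
}

#' Raw-data storage requirement
#'
#' @param frame_bytes stored frame size (default 128).
#' @param rate_hz sampling rate (default 50, the capture-mode rate).
#' @param seconds recording duration (default one day).
#' @return `budget_result` with `value` in bytes and an `mb` field at
#'   10^6 bytes/MB.
#' @export
storage_bytes <- function(frame_bytes = 128, rate_hz = 50, seconds = 86400) {
  stopifnot(frame_bytes > 0, rate_hz >= 0, seconds >= 0)
  bytes <- frame_bytes * rate_hz * seconds
  out <- budget_result("storage", bytes, "bytes",
                       sprintf("%g bytes/frame x %g Hz x %g s", frame_bytes,
                               rate_hz, seconds))
  out$mb <- bytes / 1e6
  out
}

#' Classifier model memory footprint
#'
#' @param n_sv number of support vectors.
#' @param n_features features per support vector.
#' @param bytes_per_value storage width (default 4, single-precision float).
#' @return `budget_result` in bytes with a `kb` field rounded to the nearest
#'   integer kB at 10^3 bytes/kB.
#' @export
model_memory <- function(n_sv, n_features, bytes_per_value = 4) {
  stopifnot(n_sv >= 1, n_features >= 1, bytes_per_value >= 1)
  bytes <- n_sv * n_features * bytes_per_value
  out <- budget_result("model memory", bytes, "bytes",
                       sprintf("%d SV x %d features x %d bytes/value",
                               n_sv, n_features, bytes_per_value))
  out$kb <- round(bytes / 1e3)
  out
}

#' Battery autonomy estimate
#'
#' A capacity-over-current estimate of measured hardware quantities; it is
#' reported for context, never asserted as an exact oracle (the measured
#' figures depend on the consumption profile).
#'
#' @param capacity_mAh battery capacity.
#' @param mean_current_mA mean current draw.
#' @param duty_hours_per_day hours of use per day (default continuous).
#' @return `budget_result` in hours with a `days` field.
#' @export
autonomy_hours <- function(capacity_mAh, mean_current_mA,
                           duty_hours_per_day = 24) {
  stopifnot(capacity_mAh > 0, duty_hours_per_day > 0)
  if (mean_current_mA <= 0) {
    stop("mean current must be positive", call. = FALSE)
  }
  hours <- capacity_mAh / mean_current_mA
  out <- budget_result("autonomy", hours, "h",
                       sprintf("%g mAh / %g mA", capacity_mAh,
                               mean_current_mA))
  out$days <- hours / duty_hours_per_day
  out
}

#' Tabulate the standard resource-budget quantities
#'
#' @return data.frame with quantity, value, unit and formula columns
#'   covering frame payload, daily and 3-day storage, the deployed
#'   freezing-classifier memory and the window cadence.
#' @export
budget_table <- function() {
  day <- storage_bytes()
  three <- storage_bytes(seconds = 3 * 86400)
  mm <- model_memory(211, 27, 4)
  ws <- window_spec()
  data.frame(
    quantity = c("frame payload", "frame size", "storage per day",
                 "storage per 3 days", "FoG SVM model memory",
                 "window length", "window stride"),
    value = c(payload_size(default_frame_layout()), 128, day$mb, three$mb,
              mm$kb, ws$length_s, ws$stride / ws$rate_hz),
    unit = c("bytes", "bytes", "MB", "MB", "kB", "s", "s"),
    formula = c("sum of field widths", "padded frame", day$formula,
                three$formula, mm$formula, "N / rate",
                "N (1 - overlap) / rate"))
}
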