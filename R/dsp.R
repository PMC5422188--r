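# Filtering and windowing.
#
# Streams are processed at 40 Hz (capture sessions may be recorded at 50 Hz;
# no resampling is performed -- the pipeline refuses mismatched rates). The
# low-pass stage is a 2nd-order Butterworth applied with the direct-form
# recursion y[i] = sum_j b[j] x[i-j+1] - sum_j a[j] y[i-j], whose carried
# state makes chunked (streaming) application identical to whole-stream
# application, sample for sample.

#' Construct a uniformly sampled triaxial acceleration stream
#'
#' @param x,y,z per-axis acceleration in G (equal lengths). By convention the
#'   `x` axis is the vertical (gravity-aligned) axis at the waist.
#' @param rate_hz sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return a `signal_stream` object.
#' @export
signal_stream <- function(x, y, z, rate_hz, t0 = 0) {
  stopifnot(length(y) == length(x), length(z) == length(x), rate_hz > 0)
  structure(list(axes = list(x = as.numeric(x), y = as.numeric(y),
                             z = as.numeric(z)),
                 rate_hz = rate_hz, t0 = t0),
            class = "signal_stream")
}

#' @export
print.signal_stream <- function(x, ...) {
  n <- length(x$axes$x)
  cat(sprintf("<signal_stream> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              n, x$rate_hz, n / x$rate_hz, x$t0))
  invisible(x)
}

stream_length <- function(stream) length(stream$axes$x)

#' Design a low-pass Butterworth filter
#'
#' Standard bilinear-transform design (via [signal::butter()]); unit DC gain
#' and -3 dB at the cutoff by construction.
#'
#' @param cutoff_hz cutoff frequency, strictly below Nyquist.
#' @param rate_hz sampling rate.
#' @param order filter order (default 2).
#' @return a `filter_coeffs` object with feed-forward `b` (length order + 1)
#'   and feedback `a` (length order, the leading unit coefficient dropped).
#' @export
design_lowpass <- function(cutoff_hz, rate_hz, order = 2L) {
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  filter_coeffs(bf$b, bf$a[-1])
}

#' Bundle raw filter coefficients
#'
#' @param b feed-forward coefficients.
#' @param a feedback coefficients excluding the unit leading term.
#' @return a validated `filter_coeffs` object.
#' @export
filter_coeffs <- function(b, a) {
  b <- as.numeric(b); a <- as.numeric(a)
  dc <- sum(b) / (1 + sum(a))
  if (abs(dc - 1) > 1e-9) stop("filter DC gain is not 1", call. = FALSE)
  if (any(Mod(polyroot(rev(c(1, a)))) >= 1)) {
    # roots of a_n + ... + a1 z^(n-1) + z^n are the poles of H(z)
    stop("filter is unstable (pole on or outside the unit circle)",
         call. = FALSE)
  }
  structure(list(b = b, a = a), class = "filter_coeffs")
}

#' Magnitude of the filter frequency response
#'
#' Evaluates |H(e^{i 2 pi f / rate})| analytically from the coefficients.
#'
#' @param coeffs a `filter_coeffs` object.
#' @param f_hz frequencies at which to evaluate.
#' @param rate_hz sampling rate.
#' @return magnitude response at `f_hz`.
#' @export
filter_gain <- function(coeffs, f_hz, rate_hz) {
  w <- 2 * pi * f_hz / rate_hz
  num <- vapply(w, function(wi)
    sum(coeffs$b * exp(-1i * wi * (seq_along(coeffs$b) - 1L))), complex(1))
  den <- vapply(w, function(wi)
    1 + sum(coeffs$a * exp(-1i * wi * seq_along(coeffs$a))), complex(1))
  Mod(num / den)
}

# Direct-form recursion on one axis. state carries the trailing raw and
# filtered samples so that chunked application equals one-shot application.
filter_axis <- function(x, coeffs, state = NULL) {
  nb <- length(coeffs$b)
  na <- length(coeffs$a)
  if (is.null(state)) state <- list(x = numeric(nb - 1L), y = numeric(na))
  xh <- state$x   # x[i-1], x[i-2], ...
  yh <- state$y   # y[i-1], y[i-2], ...
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- coeffs$b[1] * x[i]
    for (j in seq_len(nb - 1L)) acc <- acc + coeffs$b[j + 1L] * xh[j]
    for (j in seq_len(na)) acc <- acc - coeffs$a[j] * yh[j]
    y[i] <- acc
    if (nb > 1L) xh <- c(x[i], xh[seq_len(nb - 2L)])
    if (na > 0L) yh <- c(acc, yh[seq_len(na - 1L)])
  }
  list(y = y, state = list(x = xh, y = yh))
}

#' Apply a filter to a stream, with streaming state carry
#'
#' Pre-history defaults to zeros. Supplying the returned `state` to a
#' subsequent call continues the recursion exactly where it stopped, so
#' chunked application reproduces whole-stream application bit for bit.
#'
#' @param stream a [signal_stream()].
#' @param coeffs a `filter_coeffs` object.
#' @param state optional per-axis carry from a previous call.
#' @return list with the filtered `stream` and the updated `state`.
#' @export
apply_filter <- function(stream, coeffs, state = NULL) {
  if (is.null(state)) state <- list(x = NULL, y = NULL, z = NULL)
  out <- list()
  for (ax in c("x", "y", "z")) {
    r <- filter_axis(stream$axes[[ax]], coeffs, state[[ax]])
    out[[ax]] <- r$y
    state[[ax]] <- r$state
  }
  list(stream = signal_stream(out$x, out$y, out$z, stream$rate_hz, stream$t0),
       state = state)
}

#' Analysis window specification
#'
#' Defaults give the deployed cadence: 3.2 s windows, 50% overlap, 40 Hz,
#' i.e. N = 128 samples advancing by 64 samples (1.6 s) per window.
#'
#' @param length_s window duration in seconds.
#' @param overlap overlapped fraction of consecutive windows.
#' @param rate_hz sampling rate.
#' @return a `window_spec` with integer fields `n` and `stride`.
#' @export
window_spec <- function(length_s = 3.2, overlap = 0.5, rate_hz = 40) {
  n <- length_s * rate_hz
  stride <- n * (1 - overlap)
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) {
    stop("window length times rate must be a positive integer", call. = FALSE)
  }
  if (abs(stride - round(stride)) > 1e-9 || round(stride) < 1) {
    stop("window stride must be a positive integer number of samples",
         call. = FALSE)
  }
  structure(list(length_s = length_s, overlap = overlap, rate_hz = rate_hz,
                 n = as.integer(round(n)), stride = as.integer(round(stride))),
            class = "window_spec")
}

#' Cut a stream into overlapping analysis windows
#'
#' Windows start at multiples of the stride; trailing samples that do not
#' fill a window are dropped. For a stream of L >= N samples the count is
#' `floor((L - N) / stride) + 1`, else 0.
#'
#' @param stream a [signal_stream()] at the spec's rate.
#' @param spec a [window_spec()].
#' @return list of `window` objects with fields `index` (1-based), `start`
#'   (0-based sample offset), per-axis blocks and `rate_hz`.
#' @export
segment_windows <- function(stream, spec = window_spec()) {
  if (stream$rate_hz != spec$rate_hz) {
    stop("stream rate does not match the window spec", call. = FALSE)
  }
  L <- stream_length(stream)
  if (L < spec$n) return(list())
  starts <- seq(0L, L - spec$n, by = spec$stride)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    idx <- s + seq_len(spec$n)
    structure(list(index = i, start = s,
                   x = stream$axes$x[idx], y = stream$axes$y[idx],
                   z = stream$axes$z[idx], rate_hz = spec$rate_hz),
              class = "window")
  })
}
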