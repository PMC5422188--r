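# Per-window feature extraction.
#
# Moments use the population (1/N) denominator throughout, matching the
# on-device formulas; the evaluator's cohort summaries are the only place the
# sample (1/(N-1)) denominator appears. The discrete Fourier transform is
# indexed internally k = 0..N-1 with DC at k = 0; the device convention
# h = 1..N (DC at h = N) maps through harmonic_frequency(), and spectral
# band membership is half-open (lo, hi] in Hz.

#' Per-axis moments and signal magnitude area of a window
#'
#' Mean, population (1/N) standard deviation, range per axis, plus the signal
#' magnitude area `sma = mean(|x| + |y| + |z|)`.
#'
#' @param window a `window` from [segment_windows()].
#' @return named list: `mean`, `std`, `range` (each a named x/y/z vector)
#'   and scalar `sma`.
#' @export
basic_stats <- function(window) {
  ax <- list(x = window$x, y = window$y, z = window$z)
  mu <- vapply(ax, mean, numeric(1))
  st <- vapply(ax, pop_sd, numeric(1))
  rg <- vapply(ax, function(v) max(v) - min(v), numeric(1))
  list(mean = mu, std = st, range = rg,
       sma = mean(abs(window$x) + abs(window$y) + abs(window$z)))
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Pearson correlation with population normalisation
#'
#' `sum((x - mx)(y - my)) / (N sx sy)` with population standard deviations.
#' A zero-variance block (a still window) returns 0 rather than an error.
#'
#' @param x,y equal-length sample blocks.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  sx <- pop_sd(x); sy <- pop_sd(y)
  if (sx == 0 || sy == 0) return(0)
  r <- sum((x - mean(x)) * (y - mean(y))) / (length(x) * sx * sy)
  max(-1, min(1, r))
}

#' Population skewness
#'
#' Third standardised population moment; 0 for a constant block.
#'
#' @param x sample block.
#' @return skewness.
#' @export
skewness_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

#' Population kurtosis
#'
#' Fourth standardised population moment (not excess); 0 for a constant block.
#'
#' @param x sample block.
#' @return kurtosis.
#' @export
kurtosis_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean(((x - mean(x)) / s)^4)
}

#' Short-time Fourier transform of one window axis
#'
#' Computes X_h = sum_n x_n exp(-i 2 pi h n / N) (via the fast transform,
#' which equals direct summation to rounding error). Harmonics h = 1..N/2
#' map to frequencies `h * rate / N`; DC is harmonic N in the device's 1..N
#' indexing and k = 0 internally.
#'
#' @param block numeric sample block of length N.
#' @param rate_hz sampling rate.
#' @return a `spectrum` object: complex `values` (k = 0..N-1), `n`, `rate_hz`.
#' @export
stft <- function(block, rate_hz) {
  structure(list(values = fft(as.numeric(block)), n = length(block),
                 rate_hz = rate_hz),
            class = "spectrum")
}

#' Frequency of harmonic h in the device's 1..N indexing
#'
#' @param h harmonic index, 1..N (h = N is DC).
#' @param n window length N.
#' @param rate_hz sampling rate.
#' @return `h * rate / n` for h <= N/2; `NA` above Nyquist (mirror image);
#'   0 for h = N.
#' @export
harmonic_frequency <- function(h, n, rate_hz) {
  out <- h * rate_hz / n
  out[h > n / 2 & h < n] <- NA_real_
  out[h == n] <- 0
  out
}

#' Spectral band, half-open in frequency
#'
#' Membership is `lo < f <= hi`, matching the postural-transition band
#' (0, 0.68] Hz convention.
#'
#' @param lo_hz,hi_hz band edges with `0 <= lo < hi`.
#' @return a `band_spec`.
#' @export
band_spec <- function(lo_hz, hi_hz) {
  if (!(lo_hz >= 0 && hi_hz > lo_hz)) {
    stop("band requires 0 <= lo < hi", call. = FALSE)
  }
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz), class = "band_spec")
}

#' Default spectral band dictionary
#'
#' `postural` (0, 0.68] Hz is the printed posture-transition band. The
#' `locomotor` (0.68, 3], `freeze` (3, 8] and `dyskinetic` (1, 4] bands are
#' configurable defaults taken from the freeze-index literature, not printed
#' constants of this device.
#'
#' @return named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(postural = band_spec(0, 0.68),
       locomotor = band_spec(0.68, 3),
       freeze = band_spec(3, 8),
       dyskinetic = band_spec(1, 4))
}

band_harmonics <- function(spec, band) {
  h <- seq_len(floor(spec$n / 2))
  f <- h * spec$rate_hz / spec$n
  h[f > band$lo_hz & f <= band$hi_hz]
}

#' Spectral band energy
#'
#' Sum of |X_h|^2 over one-sided harmonics h = 1..N/2 whose frequency
#' `h * rate / N` falls in the half-open band `(lo, hi]`.
#'
#' @param spec a [stft()] spectrum.
#' @param band a [band_spec()] within (0, rate/2].
#' @return band energy (0 when no harmonic falls inside).
#' @export
band_energy <- function(spec, band) {
  if (band$hi_hz > spec$rate_hz / 2 + 1e-12) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  h <- band_harmonics(spec, band)
  if (length(h) == 0L) return(0)
  sum(Mod(spec$values[h + 1L])^2)
}

#' Ratio of two band energies
#'
#' @param spec a [stft()] spectrum.
#' @param band_a,band_b numerator and denominator [band_spec()]s.
#' @return `E_a / E_b`; `Inf` when the denominator band is empty of energy.
#' @export
band_ratio <- function(spec, band_a, band_b) {
  eb <- band_energy(spec, band_b)
  if (eb == 0) return(Inf)
  band_energy(spec, band_a) / eb
}

#' Total one-sided non-DC spectral power
#'
#' Sum of |X_h|^2 over h = 1..N/2; band energies over any disjoint partition
#' of (0, rate/2] add up to this quantity.
#'
#' @param spec a [stft()] spectrum.
#' @return total non-DC power.
#' @export
total_nondc_power <- function(spec) {
  sum(Mod(spec$values[1L + seq_len(floor(spec$n / 2))])^2)
}

#' Feature-extraction configuration
#'
#' Names the per-window features in a fixed order. The default set is a
#' documented reconstruction of the deployed feature family (the exact
#' deployed list is not published): per-axis moments, ranges, signal
#' magnitude area, pairwise correlations, skewness and kurtosis, per-axis
#' band energies over `bands`, per-axis freeze/locomotor energy ratios and
#' total non-DC power.
#'
#' @param bands named list of [band_spec()] objects.
#' @param ratios list of 2-vectors of band names, numerator first.
#' @param axes axes included for spectral features.
#' @return a `feature_config`.
#' @export
feature_config <- function(bands = default_bands(),
                           ratios = list(c("freeze", "locomotor")),
                           axes = c("x", "y", "z")) {
  for (r in ratios) {
    if (!all(r %in% names(bands))) {
      stop("ratio names must refer to configured bands", call. = FALSE)
    }
  }
  nm <- c(paste0("mean_", c("x", "y", "z")), paste0("std_", c("x", "y", "z")),
          paste0("range_", c("x", "y", "z")), "sma",
          paste0("corr_", c("xy", "xz", "yz")),
          paste0("skew_", c("x", "y", "z")), paste0("kurt_", c("x", "y", "z")),
          as.vector(t(outer(paste0("E_", names(bands)), axes, paste, sep = "_"))),
          unlist(lapply(ratios, function(r)
            paste0("ratio_", r[1], "_", r[2], "_", axes))),
          paste0("total_power_", axes))
  structure(list(bands = bands, ratios = ratios, axes = axes, names = nm),
            class = "feature_config")
}

#' Extract the configured feature vector from one window
#'
#' Deterministic and a pure function of the window samples: the same window
#' and configuration always give the identical vector, in the configuration's
#' fixed order.
#'
#' @param window a `window` from [segment_windows()].
#' @param config a [feature_config()].
#' @return named numeric feature vector.
#' @export
extract_features <- function(window, config = feature_config()) {
  bs <- basic_stats(window)
  specs <- lapply(config$axes, function(ax) stft(window[[ax]], window$rate_hz))
  names(specs) <- config$axes
  out <- c(bs$mean, bs$std, bs$range, sma = bs$sma,
           corr_xy = pearson_corr(window$x, window$y),
           corr_xz = pearson_corr(window$x, window$z),
           corr_yz = pearson_corr(window$y, window$z),
           skew_x = skewness_pop(window$x), skew_y = skewness_pop(window$y),
           skew_z = skewness_pop(window$z),
           kurt_x = kurtosis_pop(window$x), kurt_y = kurtosis_pop(window$y),
           kurt_z = kurtosis_pop(window$z))
  for (bn in names(config$bands)) {
    for (ax in config$axes) {
      out[paste0("E_", bn, "_", ax)] <-
        band_energy(specs[[ax]], config$bands[[bn]])
    }
  }
  for (r in config$ratios) {
    for (ax in config$axes) {
      # feature vectors must stay finite: an empty denominator band (a still
      # window) yields ratio 0 here, unlike the bare band_ratio() sentinel
      eb <- band_energy(specs[[ax]], config$bands[[r[2]]])
      ea <- band_energy(specs[[ax]], config$bands[[r[1]]])
      out[paste0("ratio_", r[1], "_", r[2], "_", ax)] <-
        if (eb == 0) 0 else ea / eb
    }
  }
  for (ax in config$axes) {
    out[paste0("total_power_", ax)] <- total_nondc_power(specs[[ax]])
  }
  names(out)[1:9] <- c(paste0("mean_", c("x", "y", "z")),
                       paste0("std_", c("x", "y", "z")),
                       paste0("range_", c("x", "y", "z")))
  out[config$names]
}
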