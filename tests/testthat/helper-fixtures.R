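# Shared fixtures, built in code at test time.

# A random frame whose channel values survive single-precision storage.
random_frame <- function() {
  q <- function(n) float32(round(runif(n, -8, 8), 3))
  sample_frame(acc1 = q(3), acc2 = q(3), acc3 = q(3), gyro = q(3),
               mag = q(3), baro = float32(runif(1, 900, 1100)),
               temps = q(4), battery = float32(runif(1, 3, 4.2)),
               rtc = c(sample(2000:2255, 1), sample(12, 1), sample(28, 1),
                       sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
               counter = sample(0:1e6, 1))
}

# A window object from raw per-axis sample blocks.
make_window <- function(x, y = x, z = x, rate_hz = 40, start = 0L) {
  structure(list(index = 1L, start = start, x = x, y = y, z = z,
                 rate_hz = rate_hz), class = "window")
}

random_window <- function(n = 128, rate_hz = 40) {
  make_window(rnorm(n), rnorm(n), rnorm(n), rate_hz = rate_hz)
}

# Small trained detector models, built once per test run.
.model_cache <- new.env(parent = emptyenv())
cached_models <- function() {
  if (is.null(.model_cache$models)) {
    .model_cache$models <- train_detectors(6L, seed = 101L)
  }
  .model_cache$models
}

cached_profile <- function(theta_p = NA_real_) {
  m <- cached_models()
  patient_profile(m$gait_model, m$fog_model, theta_p = theta_p)
}
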