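# Window features: moments, correlations, spectra, band energies.

test_that("basic stats use population moments exactly as defined", {
  w <- make_window(c(1, 2, 3))
  bs <- basic_stats(w)
  expect_equal(unname(bs$mean["x"]), 2)
  expect_equal(unname(bs$std["x"]), sqrt(2 / 3))
  expect_equal(unname(bs$range["x"]), 2)
  expect_equal(bs$sma, mean(3 * abs(c(1, 2, 3))))

  cw <- make_window(rep(4, 10))
  expect_equal(unname(basic_stats(cw)$std["x"]), 0)
  expect_equal(unname(basic_stats(cw)$range["x"]), 0)
})

test_that("std matches a brute-force two-pass computation on random windows", {
  withr::local_seed(1)
  for (i in 1:100) {
    v <- rnorm(64, sd = runif(1, 0.1, 5))
    expect_equal(unname(basic_stats(make_window(v))$std["x"]),
                 sqrt(sum((v - sum(v) / 64)^2) / 64), tolerance = 1e-12)
  }
})

test_that("correlation honors the printed formula and its degeneracies", {
  withr::local_seed(2)
  x <- rnorm(128)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_equal(pearson_corr(x, rep(1, 128)), 0)  # sigma = 0 convention
  for (i in 1:50) {
    a <- rnorm(64); b <- rnorm(64)
    brute <- sum((a - mean(a)) * (b - mean(b))) /
      (64 * sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
    expect_equal(pearson_corr(a, b), brute, tolerance = 1e-12)
    expect_lte(abs(pearson_corr(a, b)), 1)
  }
})

test_that("skewness and kurtosis are population standardized moments", {
  expect_equal(skewness_pop(c(1, 2, 3)), 0)
  expect_equal(skewness_pop(rep(5, 8)), 0)
  expect_equal(kurtosis_pop(rep(5, 8)), 0)
  withr::local_seed(3)
  for (i in 1:50) {
    v <- rnorm(64)
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    expect_equal(skewness_pop(v), mean(((v - m) / s)^3), tolerance = 1e-12)
    expect_equal(kurtosis_pop(v), mean(((v - m) / s)^4), tolerance = 1e-12)
  }
})

direct_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

test_that("the transform equals direct summation and satisfies Parseval", {
  withr::local_seed(4)
  # DC: constant block c has magnitude N*c in the DC term only
  sp <- stft(rep(1.5, 128), 40)
  expect_equal(Mod(sp$values[1]), 128 * 1.5)
  expect_equal(max(Mod(sp$values[-1])), 0, tolerance = 1e-9)

  # pure sinusoid at harmonic 5 concentrates there (and its conjugate)
  n <- 128
  x <- sin(2 * pi * 5 * (0:(n - 1)) / n)
  sp <- stft(x, 40)
  mags <- Mod(sp$values)
  expect_setequal(which(mags > 1e-6), c(6L, 124L))  # k = 5 and k = 123
  expect_equal(mags[6], n / 2)

  for (i in 1:100) {
    v <- rnorm(128)
    sp <- stft(v, 40)
    expect_equal(sp$values, direct_dft(v), tolerance = 1e-9)
    expect_equal(sum(v^2), sum(Mod(sp$values)^2) / 128, tolerance = 1e-9)
  }
})

test_that("harmonic-to-frequency mapping follows the 1..N device convention", {
  expect_equal(harmonic_frequency(1, 128, 40), 0.3125)
  expect_equal(harmonic_frequency(64, 128, 40), 20)
  expect_equal(harmonic_frequency(128, 128, 40), 0)     # DC is h = N
  expect_true(is.na(harmonic_frequency(100, 128, 40)))  # conjugate mirror
})

test_that("the postural band (0, 0.68] selects exactly harmonics 1 and 2", {
  # f(h) = h * 40/128: 0.3125 and 0.625 Hz are in, 0.9375 is out
  v <- rnorm(128)
  sp <- stft(v, 40)
  e <- band_energy(sp, band_spec(0, 0.68))
  expect_equal(e, sum(Mod(sp$values[c(2, 3)])^2), tolerance = 1e-12)
})

test_that("band energies partition total non-DC power; edge cases hold", {
  withr::local_seed(6)
  v <- rnorm(128)
  sp <- stft(v, 40)
  parts <- list(band_spec(0, 0.68), band_spec(0.68, 3), band_spec(3, 8),
                band_spec(8, 20))
  expect_equal(sum(vapply(parts, band_energy, numeric(1), spec = sp)),
               total_nondc_power(sp), tolerance = 1e-9)
  # full band on a zero-mean signal equals total power minus DC (the
  # one-sided sum counts the unpaired Nyquist bin once)
  v0 <- v - mean(v)
  sp0 <- stft(v0, 40)
  e_nyq <- Mod(sp0$values[65])^2
  expect_equal(band_energy(sp0, band_spec(0, 20)),
               (sum(Mod(sp0$values)^2) + e_nyq) / 2, tolerance = 1e-6)
  # empty band, invalid band, ratio sentinel
  expect_equal(band_energy(sp, band_spec(0, 0.1)), 0)
  expect_error(band_energy(sp, band_spec(0, 25)), "Nyquist")
  expect_identical(band_ratio(stft(rep(0, 128), 40), band_spec(3, 8),
                              band_spec(0.68, 3)), Inf)
})

test_that("extract_features is deterministic, complete and compositional", {
  cfg <- feature_config()
  zw <- make_window(rep(0, 128))
  fv <- extract_features(zw, cfg)
  expect_identical(names(fv), cfg$names)
  expect_true(all(fv == 0 | names(fv) %in% c()))  # zero window -> all zero
  withr::local_seed(8)
  for (i in 1:20) {
    w <- random_window()
    fv <- extract_features(w, cfg)
    expect_false(any(!is.finite(fv)))
    expect_identical(fv, extract_features(w, cfg))
    sp <- stft(w$x, 40)
    expect_equal(unname(fv["mean_x"]), mean(w$x))
    expect_equal(unname(fv["std_y"]), sqrt(mean((w$y - mean(w$y))^2)))
    expect_equal(unname(fv["corr_xz"]), pearson_corr(w$x, w$z))
    expect_equal(unname(fv["skew_z"]), skewness_pop(w$z))
    expect_equal(unname(fv["E_freeze_x"]), band_energy(sp, band_spec(3, 8)))
    expect_equal(unname(fv["ratio_freeze_locomotor_x"]),
                 band_energy(sp, band_spec(3, 8)) /
                   band_energy(sp, band_spec(0.68, 3)))
    expect_equal(unname(fv["total_power_x"]), total_nondc_power(sp))
  }
})

test_that("features are invariant to window start relabeling", {
  withr::local_seed(9)
  w1 <- random_window()
  w2 <- w1; w2$start <- 640L; w2$index <- 11L
  expect_identical(extract_features(w1), extract_features(w2))
})
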