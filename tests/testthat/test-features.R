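test_that("high-pass filter rejects DC and matches its frequency response", {
  fs <- 2000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  # DC rejection
  st <- emg_stream(rep(2.5, length(t)), fs)
  out <- highpass_filter(st, 50)$samples[1, ]
  mid <- seq(fs, length(t) - fs)
  expect_lt(max(abs(out[mid])), 1e-6 * 2.5)

  # oracle: squared magnitude response of the designed filter
  # (forward-backward application)
  bf <- signal::butter(4, 50 / (fs / 2), type = "high")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2   # squared: forward-backward pass
  }
  amp_at <- function(f) {
    y <- highpass_filter(emg_stream(sin(2 * pi * f * t), fs), 50)$samples[1, ]
    sqrt(2 * mean(y[mid]^2))
  }
  a200 <- amp_at(200)
  expect_gte(a200, 0.99); expect_lte(a200, 1.01)
  expect_equal(a200, gain2(200), tolerance = 1e-3)
  a10 <- amp_at(10)
  expect_lte(a10, 0.1)
  expect_lt(a10, 0.01)  # designed response at 10 Hz is ~3e-6
  expect_error(highpass_filter(emg_stream(sin(t), fs), 1000), "Nyquist")
})

test_that("spectral frames localize tones and reject wrong lengths", {
  fs <- 2000; n <- 256
  expect_identical(spectral_frame(rep(0, n), fs), rep(0, n / 2 + 1))
  expect_error(spectral_frame(rep(0, 100), fs, frame_size = 256), "exactly")

  # 62.5 Hz is exactly bin 8; Hann leakage is confined to +/-1 bin
  x <- sin(2 * pi * 62.5 * (0:(n - 1)) / fs)
  p <- spectral_frame(x, fs)
  expect_equal(which.max(p) - 1L, 8L)
  expect_gte(sum(p[8:10]) / sum(p), 0.99)
})

test_that("windowed Parseval identity holds on random frames", {
  set.seed(31)
  fs <- 2000; n <- 256
  w <- hann_window(n)
  for (i in 1:20) {
    x <- rnorm(n)
    p <- spectral_frame(x, fs)
    full_sum <- (p[1] + p[n / 2 + 1] + 2 * sum(p[2:(n / 2)])) / n
    expect_equal(full_sum, sum((w * x)^2), tolerance = 1e-9)
  }
})

test_that("band powers localize tones and match the direct-DFT oracle", {
  fs <- 2000; n <- 256
  expect_identical(band_powers(rep(0, n / 2 + 1), fs), rep(0, 8))

  x <- sin(2 * pi * 75 * (0:(n - 1)) / fs)
  bp <- band_powers(spectral_frame(x, fs), fs)
  expect_length(bp, 8)
  expect_gte(bp[2] / sum(bp), 0.90)  # 75 Hz lies in band [50, 100)

  set.seed(17)
  for (i in 1:25) {
    y <- rnorm(n)
    got <- band_powers(spectral_frame(y, fs), fs)
    want <- dft_band_oracle(y, fs)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-300)), 1e-9)
  }
  expect_error(band_powers(rep(1, 129), 600, f_max = 400), "Nyquist")
})

test_that("feature stream has the documented shape and frame count", {
  fs <- 2000
  set.seed(12)
  st3 <- emg_stream(matrix(rnorm(3 * 2048), nrow = 3), fs)
  fstr <- extract_feature_stream(st3)
  expect_equal(ncol(fstr$features), 24L)
  expect_equal(nrow(fstr$features), (2048L - 256L) %/% 128L + 1L)  # 15
  st1 <- emg_stream(rnorm(1024), fs)
  expect_equal(ncol(extract_feature_stream(st1)$features), 8L)
  expect_error(extract_feature_stream(emg_stream(rnorm(100), fs)),
               "shorter")
})

test_that("feature values are non-negative, bounded, and scale as amplitude squared", {
  fs <- 2000
  set.seed(23)
  x <- matrix(rnorm(3 * 1024), nrow = 3)
  st <- emg_stream(x, fs)
  fstr <- extract_feature_stream(st)
  expect_true(all(fstr$features >= 0))

  # energy bound: banded mass never exceeds total windowed spectral power
  hp <- highpass_filter(st, 50)
  freqs <- seq(0, 128) * fs / 256
  counts <- as.vector(table(floor(freqs[freqs < 400] / 50)))
  for (ch in 1:3) {
    sp <- spectral_frame(hp$samples[ch, 1:256], fs)
    bp <- band_powers(sp, fs)
    expect_lte(sum(bp * counts), sum(sp) + 1e-9)
  }

  # amplitude equivariance: c * input -> c^2 * band powers
  f2 <- extract_feature_stream(emg_stream(3 * x, fs))
  expect_equal(f2$features, 9 * fstr$features, tolerance = 1e-9)
})

test_that("feature configuration is validated", {
  expect_error(feature_config(frame_size = 200), "power of two")
  expect_error(feature_config(hop = 0), "hop")
  expect_error(feature_config(hop = 512), "hop")
})
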