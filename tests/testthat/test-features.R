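test_that("the band-pass keeps 20 Hz and rejects 50 Hz", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  mk <- function(f) {
    r <- simulate_recording("rest", 10, sim_params(noise_sd = 0))
    r$amplitude <- cos(2 * pi * f * t)
    r
  }
  # steady-state gain measured on the signal tail vs the analytic response
  gain_at <- function(f) {
    y <- bandpass(mk(f))$amplitude
    max(abs(tail(y, 2000)))
  }
  # analytic transfer-function magnitude |H(e^{jw})| from the coefficients
  bf <- signal::butter(3, c(17, 23) / 500, "pass")
  hmag <- function(f) {
    z <- exp(1i * 2 * pi * f / fs)
    Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
          sum(bf$a * z^-(seq_along(bf$a) - 1)))
  }
  g20 <- gain_at(20)
  expect_equal(g20, hmag(20), tolerance = 1e-3)
  expect_gte(g20, 0.9)
  expect_lte(g20, 1.0)
  g50 <- gain_at(50)
  expect_equal(g50, hmag(50), tolerance = 0.05)
  expect_gte(-20 * log10(g50), 20) # >= 20 dB attenuation

  # causal, linear, length preserving
  zero <- mk(20); zero$amplitude <- rep(0, length(t))
  expect_true(all(bandpass(zero)$amplitude == 0))
  r <- mk(20)
  expect_lt(max(abs(
    bandpass({ r2 <- r; r2$amplitude <- 3 * r$amplitude; r2 })$amplitude -
      3 * bandpass(r)$amplitude
  )), 1e-6)
  expect_equal(nrow(bandpass(r)), length(t))
  expect_error(bandpass(r, band = c(400, 600)), "Nyquist")
})

test_that("extract_component matches an independent FFT oracle", {
  k <- 200; fs <- 1000; f0 <- 20
  cases <- list(
    cos(2 * pi * f0 * (1:k) / fs),
    cos(2 * pi * f0 * (1:k) / fs + pi / 2),
    withr::with_seed(1, rnorm(k)),
    sin(2 * pi * f0 * (1:k) / fs) + withr::with_seed(2, rnorm(k, 0, 0.3))
  )
  for (s in cases) {
    ours <- extract_component(s, f0, fs)
    oracle <- fft_component_oracle(s, f0, fs)
    expect_lt(Mod(ours - oracle) / max(Mod(oracle), 1e-300), 1e-10)
  }

  # a pure cosine at f0: amplitude ~ Hamming coherent sum / 2K, phase ~ 0
  f <- extract_component(cos(2 * pi * f0 * (1:k) / fs), f0, fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(k - 1)) / (k - 1))
  expect_equal(Mod(f), sum(w) / (2 * k), tolerance = 1e-3)
  expect_phase_equal(Arg(f) * 180 / pi, 0, tol = 0.1)
  # +90 degrees in, +90 degrees out (vs the same oracle, tight)
  f90 <- extract_component(cos(2 * pi * f0 * (1:k) / fs + pi / 2), f0, fs)
  o90 <- fft_component_oracle(cos(2 * pi * f0 * (1:k) / fs + pi / 2), f0, fs)
  expect_phase_equal(Arg(f90) * 180 / pi, Arg(o90) * 180 / pi, tol = 1e-6)
  expect_phase_equal(Arg(f90) * 180 / pi - Arg(f) * 180 / pi, 90, tol = 0.2)

  expect_equal(extract_component(rep(0, k)), 0 + 0i)
  expect_error(extract_component(numeric(0)), "non-empty")
})

test_that("window counts match brute-force enumeration", {
  rec_of <- function(n) {
    r <- simulate_recording("rest", n / 1000, sim_params(noise_sd = 1, seed = 1))
    r
  }
  # reference protocol: 30 s -> 597 windows
  expect_equal(nrow(vectors_from_recording(rec_of(30000))), 597)
  # boundary: exactly one window
  expect_equal(nrow(vectors_from_recording(rec_of(200))), 1)
  expect_error(vectors_from_recording(rec_of(100)), "shorter")

  brute <- function(n, k, step) length(seq(0, n - k, by = step))
  grid <- expand.grid(n = c(200, 250, 999, 1000, 5000),
                      k = c(100, 200), overlap = c(0, 0.5, 0.75))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    step <- g$k * (1 - g$overlap)
    got <- nrow(vectors_from_recording(rec_of(g$n), k = g$k,
                                       overlap = g$overlap))
    expect_equal(got, brute(g$n, g$k, step))
    expect_equal(got, floor((g$n - g$k) / step) + 1)
  }
})

test_that("phase is equivariant under sample shifts", {
  fs <- 1000; f0 <- 20; k <- 200
  # advancing the window by m samples rotates the phase by +360 f0 m / fs
  # (delaying the signal gives the negative); for a real sinusoid the
  # negative-frequency leakage through the Hamming window adds a
  # position-dependent residual of a few millidegrees, hence the tolerance
  y <- sin(2 * pi * f0 * (1:2000) / fs)
  b0 <- Arg(extract_component(y[1:k], f0, fs)) * 180 / pi
  for (m in c(1, 7, 25, 50)) {
    bm <- Arg(extract_component(y[(1 + m):(k + m)], f0, fs)) * 180 / pi
    expect_phase_equal(bm - b0, 360 * f0 * m / fs, tol = 0.01)
  }
  # for a complex exponential the rotation is exact to numerical precision
  z <- exp(1i * 2 * pi * f0 * (1:2000) / fs)
  c0 <- Arg(extract_component(z[1:k], f0, fs)) * 180 / pi
  for (m in c(1, 7, 25)) {
    cm <- Arg(extract_component(z[(1 + m):(k + m)], f0, fs)) * 180 / pi
    expect_phase_equal(cm - c0, 360 * f0 * m / fs, tol = 1e-9)
  }
})

test_that("phase calibration subtracts the reference and preserves spread", {
  expect_equal(calibrate_phases(c(10, 350), 0), c(10, 350))
  ph <- c(10, 350)
  # circular mean of {10, 350} is 0, so calibrating by it is the identity
  expect_equal(calibrate_phases(ph, 0), ph)
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- runif(50, 0, 360)
      ref <- runif(1, 0, 360)
      y <- calibrate_phases(x, ref)
      circ_var <- function(p) 1 - Mod(mean(exp(1i * p * pi / 180)))
      expect_equal(circ_var(y), circ_var(x), tolerance = 1e-12)
      expect_true(all(y >= 0 & y < 360))
    }
  })
})
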