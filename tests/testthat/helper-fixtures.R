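# Shared fixtures, all generated in code.

# Well-separated synthetic feature clusters: four gaze classes at the
# quadrature phases with high amplitude, plus a low-amplitude uniform-phase
# rest class.
separable_vectors <- function(n_per_class = 100, phase_sd = 5,
                              phases = c(0, 90, 180, 270) + 45, seed = 42) {
  withr::with_seed(seed, {
    gaze <- purrr::map_dfr(seq_along(phases), function(i) {
      tibble::tibble(
        amplitude = stats::rnorm(n_per_class, 1, 0.05),
        phase_deg = ((stats::rnorm(n_per_class, phases[i], phase_sd)) %% 360),
        label = as.character(i)
      )
    })
    rest <- tibble::tibble(
      amplitude = abs(stats::rnorm(n_per_class, 0.1, 0.05)),
      phase_deg = stats::runif(n_per_class, 0, 360),
      label = "rest"
    )
    dplyr::bind_rows(gaze, rest)
  })
}

# Small, fast experiment configuration used by end-to-end tests: shorter
# recordings and no hyperparameter search keep the suite quick while leaving
# every stage of the pipeline in place.
fast_config <- function(seed = 1, noise_sd = 0, record_s = 20,
                        n_trials_per_class = 5, offset = 20, ...) {
  experiment_config(
    seed = seed,
    simulation = list(noise_sd = noise_sd, subject_phase_offset = offset),
    svm = list(tune = FALSE),
    session = list(record_s = record_s,
                   n_trials_per_class = n_trials_per_class),
    ...
  )
}

# Brute-force windowed DFT via stats::fft, used as the independent oracle for
# extract_component(): identical Hamming weighting, but the frequency bin is
# read from a full FFT (index convention n = 0..K-1, corrected to n = 1..K).
fft_component_oracle <- function(s, f0 = 20, fs = 1000) {
  k <- length(s)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(k - 1)) / (k - 1))
  bin <- f0 * k / fs
  stopifnot(abs(bin - round(bin)) < 1e-9)
  x <- stats::fft(w * s)[round(bin) + 1]
  x * exp(-2i * pi * f0 / fs) / k
}

expect_phase_equal <- function(a, b, tol = 1e-6) {
  d <- ((a - b + 180) %% 360) - 180
  expect_lt(max(abs(d)), tol)
}
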