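#' Stimulus configuration for a phase-tagged flicker panel
#'
#' Describes a panel of `S` visual flickers that all flash at the same
#' frequency `f0` but carry distinct phase tags, so that the gazed target can
#' be decoded from the SSVEP phase rather than its frequency. The default is
#' the canonical four-target layout: 20 Hz flicker, phase tags 0, 90, 180 and
#' 270 degrees, sampled at 1 kHz.
#'
#' @param f0 Flicker frequency in Hz.
#' @param fs Sampling frequency of the EEG acquisition in Hz; must exceed
#'   `2 * f0`.
#' @param phases Ordered numeric vector of phase tags in degrees, all in
#'   `[0, 360)` and pairwise distinct. Target `i` carries `phases[i]`.
#' @return An object of class `stimulus_config`: a list with elements `f0`,
#'   `fs`, `phases` and `n_targets`.
#' @examples
#' cfg <- stimulus_config()
#' cfg$phases
#' @export
stimulus_config <- function(f0 = 20, fs = 1000, phases = c(0, 90, 180, 270)) {
  stopifnot_scalar_number(f0, "f0", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(fs, "fs", min = 0, strict_min = TRUE)
  if (fs <= 2 * f0) abort("`fs` must exceed 2 * f0 (Nyquist).")
  if (!is.numeric(phases) || length(phases) < 1L || anyNA(phases)) {
    abort("`phases` must be a non-empty numeric vector.")
  }
  if (any(phases < 0 | phases >= 360)) abort("`phases` must lie in [0, 360).")
  if (anyDuplicated(phases)) abort("`phases` must be pairwise distinct.")
  structure(
    list(f0 = f0, fs = fs, phases = as.numeric(phases),
         n_targets = length(phases)),
    class = "stimulus_config"
  )
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf(
    "<stimulus_config> %d targets @ %g Hz (fs = %g Hz), phase tags: %s deg\n",
    x$n_targets, x$f0, x$fs, paste(x$phases, collapse = ", ")
  ))
  invisible(x)
}

#' Latency implementing a phase tag
#'
#' A phase tag of `theta` degrees at flicker frequency `f0` is realised by
#' delaying the flicker sequence by `t = theta / 360 * T` where `T = 1 / f0`
#' is the flicker period. At 20 Hz the four quadrature tags 0/90/180/270
#' degrees correspond to delays of 0, 12.5, 25 and 37.5 ms.
#'
#' @param theta Phase tag in degrees, in `[0, 360)`. Vectorised.
#' @param f0 Flicker frequency in Hz.
#' @return Latency in milliseconds, in `[0, 1000 / f0)`.
#' @examples
#' latency_for_phase(c(0, 90, 180, 270), 20)
#' @export
latency_for_phase <- function(theta, f0 = 20) {
  if (!is.numeric(theta) || length(theta) == 0L || any(!is.finite(theta))) {
    abort("`theta` must be finite numeric degrees.")
  }
  if (any(theta < 0 | theta >= 360)) abort("`theta` must lie in [0, 360).")
  stopifnot_scalar_number(f0, "f0", min = 0, strict_min = TRUE)
  theta / 360 * (1000 / f0)
}

#' Flash-onset trigger train for one flicker
#'
#' Flash onsets (OFF-to-ON transitions) of target `led_index` occur at
#' `latency_for_phase(theta_led) + k * (1000 / f0)` milliseconds for
#' `k = 0, 1, ...`. Onset times are computed in continuous milliseconds,
#' optionally perturbed by independent Gaussian jitter, then rounded half-up
#' to the nearest sample of the `fs` grid. Onsets at or beyond the recording
#' duration are dropped.
#'
#' @param config A [stimulus_config()].
#' @param led_index 1-based target index in `1..S`.
#' @param duration_s Recording duration in seconds.
#' @param jitter_sd_ms Standard deviation of per-onset Gaussian timing jitter
#'   in milliseconds; `0` (the default) models an ideal stimulator.
#' @param seed Optional integer seed making jittered trains reproducible.
#' @return A tibble of class `trigger_train` with columns `led` and
#'   `onset_sample` (0-based sample indices, strictly increasing).
#' @examples
#' tr <- generate_triggers(stimulus_config(), led_index = 2, duration_s = 1)
#' head(tr)
#' @export
generate_triggers <- function(config = stimulus_config(), led_index = 1,
                              duration_s, jitter_sd_ms = 0, seed = NULL) {
  stopifnot(inherits(config, "stimulus_config"))
  if (!is.numeric(led_index) || length(led_index) != 1L ||
      led_index < 1 || led_index > config$n_targets ||
      led_index != round(led_index)) {
    abort(sprintf("`led_index` must be an integer in 1..%d.", config$n_targets))
  }
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(jitter_sd_ms, "jitter_sd_ms", min = 0)

  period_ms <- 1000 / config$f0
  t0_ms <- latency_for_phase(config$phases[led_index], config$f0)
  duration_ms <- duration_s * 1000
  k <- seq.int(0L, ceiling(duration_ms / period_ms))
  onset_ms <- t0_ms + k * period_ms
  if (jitter_sd_ms > 0) {
    onset_ms <- with_seed_if(seed, onset_ms + rnorm(length(onset_ms), 0, jitter_sd_ms))
  }
  onset_sample <- round_half_up(onset_ms * config$fs / 1000)
  onset_sample <- onset_sample[onset_sample >= 0 &
                                 onset_sample < round(duration_s * config$fs)]
  onset_sample <- sort(onset_sample)
  out <- tibble::tibble(led = as.integer(led_index),
                        onset_sample = as.integer(onset_sample))
  class(out) <- c("trigger_train", class(out))
  out
}
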