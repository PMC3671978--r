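#' Simulation parameters for synthetic Oz EEG
#'
#' Parameters of the single-channel occipital EEG generator. Gazing at a
#' phase-tagged flicker produces a steady-state visual evoked potential
#' (SSVEP): a sinusoid at the flicker frequency whose phase is the stimulus
#' phase tag plus a constant per-subject visual-pathway offset. The resting
#' (non-gaze) condition carries no SSVEP, so its phase at the flicker
#' frequency is uniformly distributed. Background EEG is modelled as
#' stationary Gaussian noise band-limited to the acquisition pre-filter band.
#'
#' @param ssvep_amplitude SSVEP amplitude in microvolts.
#' @param subject_phase_offset Constant phase offset in degrees added to every
#'   gaze class, representing the subject's visual-pathway delay. `NULL`
#'   (default) draws one offset uniformly on `[0, 360)` under `seed`.
#' @param noise_sd Standard deviation of the background noise in microvolts.
#'   The default 1.25 is calibrated so that the end-to-end synthetic pipeline
#'   performs in the accuracy range reported for real subjects.
#' @param noise_band Length-2 Hz vector; noise is band-limited to this band,
#'   mirroring a 0.1--100 Hz acquisition pre-filter.
#' @param phase_jitter_sd Per-cycle SSVEP phase wobble in degrees (0 = rigid
#'   phase locking).
#' @param one_over_f If `TRUE`, shape the noise spectrum as 1/f (power) before
#'   band-limiting; off by default.
#' @param seed Integer seed for all randomness tied to these parameters.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(ssvep_amplitude = 1.0, subject_phase_offset = NULL,
                       noise_sd = 1.25, noise_band = c(0.1, 100),
                       phase_jitter_sd = 0, one_over_f = FALSE, seed = 1L) {
  stopifnot_scalar_number(ssvep_amplitude, "ssvep_amplitude", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(phase_jitter_sd, "phase_jitter_sd", min = 0)
  if (length(noise_band) != 2L || noise_band[1] <= 0 ||
      noise_band[2] <= noise_band[1]) {
    abort("`noise_band` must be an increasing positive Hz pair.")
  }
  if (is.null(subject_phase_offset)) {
    subject_phase_offset <- with_seed_if(seed + 10007L, runif(1, 0, 360))
  }
  stopifnot_scalar_number(subject_phase_offset, "subject_phase_offset",
                          min = 0, max = 360)
  subject_phase_offset <- wrap_deg(subject_phase_offset)
  structure(
    list(ssvep_amplitude = ssvep_amplitude,
         subject_phase_offset = subject_phase_offset,
         noise_sd = noise_sd, noise_band = as.numeric(noise_band),
         phase_jitter_sd = phase_jitter_sd, one_over_f = one_over_f,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> amplitude %g uV, noise sd %g uV (%g-%g Hz%s), ",
           "subject offset %.1f deg, phase jitter sd %g deg, seed %d\n"),
    x$ssvep_amplitude, x$noise_sd, x$noise_band[1], x$noise_band[2],
    if (x$one_over_f) ", 1/f" else "", x$subject_phase_offset,
    x$phase_jitter_sd, x$seed
  ))
  invisible(x)
}

new_recording <- function(amplitude, fs, condition, triggers) {
  out <- tibble::tibble(
    sample = seq_along(amplitude) - 1L,
    amplitude = as.numeric(amplitude)
  )
  class(out) <- c("eeg_recording", class(out))
  attr(out, "fs") <- fs
  attr(out, "condition") <- condition
  attr(out, "triggers") <- triggers
  out
}

#' Sampling rate, condition label and trigger train of a recording
#'
#' @param recording An `eeg_recording` as returned by [simulate_recording()]
#'   or [read_signal()].
#' @return `recording_fs()` the sampling rate in Hz; `recording_condition()`
#'   the condition label; `recording_triggers()` the reference trigger train.
#' @export
recording_fs <- function(recording) attr(recording, "fs")

#' @rdname recording_fs
#' @export
recording_condition <- function(recording) attr(recording, "condition")

#' @rdname recording_fs
#' @export
recording_triggers <- function(recording) attr(recording, "triggers")

# Band-limited stationary Gaussian noise, rescaled to sd = noise_sd.
make_noise <- function(n, fs, noise_sd, noise_band, one_over_f = FALSE) {
  if (noise_sd == 0) return(numeric(n))
  x <- rnorm(n)
  if (one_over_f) {
    spec <- stats::fft(x)
    freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
    shape <- 1 / sqrt(pmax(freq, noise_band[1]))
    x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  }
  hi <- min(noise_band[2], 0.99 * fs / 2)
  bf <- signal::butter(2, c(noise_band[1], hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, x))
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * noise_sd / s
}

normalize_condition <- function(condition, config) {
  if (identical(condition, "rest")) return("rest")
  cond <- suppressWarnings(as.integer(condition))
  if (is.na(cond) || cond < 1L || cond > config$n_targets) {
    abort(sprintf(
      "`condition` must be \"rest\" or a target index in 1..%d, got %s.",
      config$n_targets, deparse(condition)
    ))
  }
  as.character(cond)
}

#' Simulate a single-condition Oz-EEG recording
#'
#' For a gaze condition `c`, the sample at time `t` is
#' `A cos(2 pi f0 t + theta_c + phi_subject + jitter)` plus band-limited
#' Gaussian noise; for the resting condition it is noise alone. The returned
#' recording carries the reference (target 1) flash-onset trigger train.
#'
#' @param condition Target index in `1..S`, or `"rest"`.
#' @param duration_s Duration in seconds.
#' @param params A [sim_params()].
#' @param config A [stimulus_config()].
#' @param seed Optional override of `params$seed`.
#' @return An `eeg_recording` tibble with columns `sample` and `amplitude`
#'   plus `fs`, `condition` and `triggers` attributes.
#' @examples
#' rec <- simulate_recording(1, 2, sim_params(noise_sd = 0, seed = 1))
#' recording_condition(rec)
#' @export
simulate_recording <- function(condition, duration_s, params = sim_params(),
                               config = stimulus_config(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(config, "stimulus_config"))
  stopifnot_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  condition <- normalize_condition(condition, config)
  seed <- if (is.null(seed)) params$seed else as.integer(seed)

  n <- round(duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  x <- with_seed_if(seed, {
    noise <- make_noise(n, config$fs, params$noise_sd, params$noise_band,
                        params$one_over_f)
    if (condition == "rest") {
      noise
    } else {
      theta <- config$phases[as.integer(condition)] +
        params$subject_phase_offset
      phase_rad <- theta * pi / 180
      if (params$phase_jitter_sd > 0) {
        cyc <- floor(t * config$f0)
        wob <- rnorm(max(cyc) + 1L, 0, params$phase_jitter_sd) * pi / 180
        phase_rad <- phase_rad + wob[cyc + 1L]
      }
      params$ssvep_amplitude * cos(2 * pi * config$f0 * t + phase_rad) + noise
    }
  })
  triggers <- generate_triggers(config, 1L, duration_s)
  new_recording(x, config$fs, condition, triggers)
}

#' Simulate a full online application session
#'
#' Emulates the cue-driven online protocol: `S * n_trials_per_class` trials in
#' randomized order, each class cued equally often. Each trial starts with a
#' gaze-shift transition span (noise only, no SSVEP) followed by phase-locked
#' gaze signal lasting `gaze_s` seconds, long enough for the effective-epoch
#' detector to reach a decision or run out of vectors. The SSVEP phase is
#' locked to the global stimulus clock, so trial boundaries fall on flicker
#' cycles.
#'
#' @param params A [sim_params()].
#' @param config A [stimulus_config()].
#' @param n_trials_per_class Trials per target (default 20, i.e. 80 trials for
#'   four targets).
#' @param gaze_s Gaze span per trial in seconds.
#' @param transition_s Transition span per trial in seconds (default 0.5).
#' @param seed Optional override of `params$seed`.
#' @return An object of class `bci_session`: list with elements `recording`
#'   (one continuous `eeg_recording`), `trials` (tibble with `trial`,
#'   `cue_class`, `start_sample`, `end_sample`), `config`, `params`,
#'   `transition_s` and `gaze_s`.
#' @export
simulate_online_session <- function(params = sim_params(),
                                    config = stimulus_config(),
                                    n_trials_per_class = 20,
                                    gaze_s = 4, transition_s = 0.5,
                                    seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(config, "stimulus_config"))
  if (n_trials_per_class < 1 || n_trials_per_class != round(n_trials_per_class)) {
    abort("`n_trials_per_class` must be a positive integer.")
  }
  stopifnot_scalar_number(gaze_s, "gaze_s", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(transition_s, "transition_s", min = 0)
  seed <- if (is.null(seed)) params$seed else as.integer(seed)

  fs <- config$fs
  cycle <- fs / config$f0
  # keep trial boundaries on the flicker-cycle grid
  trans_n <- round(transition_s * fs / cycle) * cycle
  gaze_n <- round(gaze_s * fs / cycle) * cycle
  trial_n <- trans_n + gaze_n
  s <- config$n_targets
  n_trials <- s * n_trials_per_class
  total_n <- n_trials * trial_n

  sim <- with_seed_if(seed, {
    cues <- sample(rep(seq_len(s), n_trials_per_class))
    noise <- make_noise(total_n, fs, params$noise_sd, params$noise_band,
                        params$one_over_f)
    t <- (seq_len(total_n) - 1) / fs
    x <- noise
    for (k in seq_len(n_trials)) {
      g0 <- (k - 1) * trial_n + trans_n # 0-based gaze start
      idx <- (g0 + 1):(g0 + gaze_n)
      theta <- config$phases[cues[k]] + params$subject_phase_offset
      phase_rad <- theta * pi / 180
      if (params$phase_jitter_sd > 0) {
        cyc <- floor(t[idx] * config$f0)
        cyc <- cyc - min(cyc)
        wob <- rnorm(max(cyc) + 1L, 0, params$phase_jitter_sd) * pi / 180
        phase_rad <- phase_rad + wob[cyc + 1L]
      }
      x[idx] <- x[idx] +
        params$ssvep_amplitude * cos(2 * pi * config$f0 * t[idx] + phase_rad)
    }
    list(x = x, cues = cues)
  })

  trials <- tibble::tibble(
    trial = seq_len(n_trials),
    cue_class = as.character(sim$cues),
    start_sample = as.integer((seq_len(n_trials) - 1) * trial_n),
    end_sample = as.integer(seq_len(n_trials) * trial_n - 1L)
  )
  recording <- new_recording(sim$x, fs, "online_session",
                             generate_triggers(config, 1L, total_n / fs))
  structure(
    list(recording = recording, trials = trials, config = config,
         params = params, transition_s = trans_n / fs, gaze_s = gaze_n / fs),
    class = "bci_session"
  )
}

#' @export
print.bci_session <- function(x, ...) {
  counts <- table(x$trials$cue_class)
  cat(sprintf(
    "<bci_session> %d trials (%s per class), %.1f s of EEG @ %g Hz\n",
    nrow(x$trials), paste(unique(counts), collapse = "/"),
    nrow(x$recording) / recording_fs(x$recording), recording_fs(x$recording)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bci_session <- function(x, ...) x$trials
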