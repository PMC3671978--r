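#' Causal Butterworth band-pass filter
#'
#' Filters the recording forward-only (causal IIR), as an online decoder
#' must: no zero-phase `filtfilt` refinement is applied, so the filter's
#' group delay shifts every extracted phase by a common constant that the
#' classifier absorbs. The default is a 6th-order (overall) Butterworth
#' band-pass at 17--23 Hz isolating the 20 Hz SSVEP.
#'
#' @param recording An `eeg_recording`.
#' @param band Length-2 Hz passband; must lie inside `(0, fs / 2)`.
#' @param order Overall band-pass filter order (even; the low/high prototype
#'   is of order `order / 2`).
#' @return The filtered recording, same length and attributes.
#' @export
bandpass <- function(recording, band = c(17, 23), order = 6) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording_fs(recording)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    abort("`band` must be an increasing positive Hz pair.")
  }
  if (band[2] >= fs / 2) abort("`band` must lie below the Nyquist frequency.")
  if (order < 2 || order %% 2 != 0) abort("`order` must be a positive even integer.")
  if (nrow(recording) <= 3 * order) abort("Recording too short to filter.")
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  out <- recording
  out$amplitude <- as.numeric(signal::filter(bf, recording$amplitude))
  attr(out, "band") <- band
  out
}

# Hamming window, symmetric convention w[n] = 0.54 - 0.46 cos(2 pi n/(K-1)).
hamming_window <- function(k) {
  if (k == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(k - 1)) / (k - 1))
}

#' Windowed Fourier component at the flicker frequency
#'
#' Computes `F = (1/K) sum_{n=1}^{K} w[n] s[n] exp(-j 2 pi (f0/fs) n)` for one
#' analysis window `s` of length `K`, with `w` the Hamming window. The
#' amplitude `|F|` and phase `angle(F)` of this single frequency bin are the
#' two features the decoder uses. The `1/K` normalisation is kept as is (no
#' coherent-gain correction): the absolute amplitude scale is irrelevant to
#' classification.
#'
#' @param window_samples Numeric vector, one analysis window.
#' @param f0 Analysis frequency in Hz.
#' @param fs Sampling frequency in Hz.
#' @return A single complex number.
#' @examples
#' s <- cos(2 * pi * 20 * (1:200) / 1000)
#' Mod(extract_component(s)) # ~ mean(hamming)/2
#' @export
extract_component <- function(window_samples, f0 = 20, fs = 1000) {
  k <- length(window_samples)
  if (k < 1L) abort("`window_samples` must be non-empty.")
  if (anyNA(window_samples)) abort("`window_samples` contains NA.")
  n <- seq_len(k)
  sum(hamming_window(k) * window_samples * exp(-2i * pi * (f0 / fs) * n)) / k
}

#' Sliding-window input vectors from a recording
#'
#' Slides a `K`-sample Hamming window (default 200 samples = 4 flicker cycles
#' at 20 Hz / 1 kHz) across the filtered recording with 75% overlap (step =
#' one cycle) and emits one `(amplitude, phase)` input vector per window via
#' [extract_component()]. Windows are aligned to the start of the recording;
#' a 30 s recording yields 597 vectors.
#'
#' @param recording A (band-pass filtered) `eeg_recording`.
#' @param k Window length in samples.
#' @param overlap Window overlap fraction in `[0, 1)`; `k * (1 - overlap)`
#'   must be a whole number of samples.
#' @param f0 Analysis frequency in Hz (defaults to 20).
#' @param transition_exclude Number of leading vectors to drop (used online to
#'   skip the gaze-shift transition; keep 0 for offline recordings).
#' @return A tibble with columns `window_index` (0-based), `start_sample`,
#'   `amplitude`, `phase_deg` (in `[0, 360)`) and `label` (the recording's
#'   condition).
#' @export
vectors_from_recording <- function(recording, k = 200, overlap = 0.75,
                                   f0 = 20, transition_exclude = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording_fs(recording)
  step <- k * (1 - overlap)
  if (overlap < 0 || overlap >= 1 || abs(step - round(step)) > 1e-9) {
    abort("`k * (1 - overlap)` must be a whole number of samples.")
  }
  step <- as.integer(round(step))
  n <- nrow(recording)
  if (n < k) abort("Recording shorter than one analysis window.")

  starts <- seq.int(0L, n - k, by = step)
  w <- hamming_window(k)
  rot <- exp(-2i * pi * (f0 / fs) * seq_len(k))
  x <- recording$amplitude
  comp <- purrr::map_vec(starts, function(s0) {
    sum(w * x[(s0 + 1):(s0 + k)] * rot) / k
  })
  out <- tibble::tibble(
    window_index = seq_along(starts) - 1L,
    start_sample = as.integer(starts),
    amplitude = Mod(comp),
    phase_deg = wrap_deg(Arg(comp) * 180 / pi),
    label = recording_condition(recording)
  )
  if (transition_exclude > 0) out <- out[-seq_len(min(transition_exclude, nrow(out))), ]
  out
}

#' Sliding-window input vectors for every trial of an online session
#'
#' Extracts input vectors over the whole session recording on the global
#' window grid (so windows stay locked to the reference trigger train), then
#' assigns each vector to the trial that fully contains its window and drops
#' the first `transition_exclude` vectors of every trial (the 0.5 s gaze-shift
#' transition, 10 vectors at the default window step).
#'
#' @param session A `bci_session` from [simulate_online_session()].
#' @param band,order Band-pass settings passed to [bandpass()].
#' @param k,overlap,f0 Window settings passed to [vectors_from_recording()].
#' @param transition_exclude Leading vectors dropped per trial.
#' @return A tibble like [vectors_from_recording()] with extra columns
#'   `trial` and `cue_class`, and `label` set to the trial's cue.
#' @export
vectors_from_session <- function(session, band = c(17, 23), order = 6,
                                 k = 200, overlap = 0.75, f0 = 20,
                                 transition_exclude = 10) {
  stopifnot(inherits(session, "bci_session"))
  filtered <- bandpass(session$recording, band = band, order = order)
  vecs <- vectors_from_recording(filtered, k = k, overlap = overlap, f0 = f0)
  trials <- session$trials
  vecs <- dplyr::inner_join(
    vecs,
    dplyr::select(trials, "trial", "cue_class", "start_sample2" = "start_sample",
                  "end_sample"),
    by = dplyr::join_by("start_sample" >= "start_sample2",
                        "start_sample" <= "end_sample")
  )
  vecs <- dplyr::filter(vecs, .data$start_sample + k - 1L <= .data$end_sample)
  vecs <- dplyr::group_by(vecs, .data$trial)
  vecs <- dplyr::filter(vecs, dplyr::row_number() > transition_exclude)
  vecs <- dplyr::ungroup(vecs)
  dplyr::transmute(vecs,
                   trial = .data$trial,
                   cue_class = .data$cue_class,
                   window_index = .data$window_index,
                   start_sample = .data$start_sample,
                   amplitude = .data$amplitude,
                   phase_deg = .data$phase_deg,
                   label = .data$cue_class)
}

#' Calibrate phases to a reference
#'
#' Subtracts a reference phase (typically the circular mean of the target-1
#' phases of the same subject) so that phase features become comparable
#' across subjects despite individual visual-pathway delays.
#'
#' @param phases Numeric phases in degrees.
#' @param reference Reference phase in degrees.
#' @return `(phases - reference) mod 360`, in `[0, 360)`.
#' @export
calibrate_phases <- function(phases, reference) {
  if (!is.numeric(phases)) abort("`phases` must be numeric degrees.")
  stopifnot_scalar_number(reference, "reference")
  wrap_deg(phases - reference)
}
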