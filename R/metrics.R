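#' Wolpaw bits per command
#'
#' Information content of one command selection among `S` targets at accuracy
#' `P`: `log2 S + P log2 P + (1 - P) log2((1 - P)/(S - 1))`, with the
#' convention `0 log 0 = 0` so that `P = 0` and `P = 1` are well defined.
#' The formula attains its minimum, 0 bits, at chance (`P = 1/S`) and is
#' non-monotone below chance; below-chance values are reported as computed,
#' never clipped.
#'
#' @param p Accuracy as a fraction in `[0, 1]`. Vectorised.
#' @param s Number of selectable targets (>= 2).
#' @return Bits per command.
#' @examples
#' bits_per_command(c(0.25, 1), s = 4) # chance = 0 bits, perfect = 2 bits
#' @export
bits_per_command <- function(p, s = 4) {
  if (s < 2 || s != round(s)) abort("`s` must be an integer >= 2.")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be a fraction in [0, 1].")
  }
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(s) + xlx(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (s - 1)), 0)
}

#' Information transfer rate
#'
#' `ITR = bits_per_command * 60 / CTI` in bits per minute, where the command
#' transfer interval CTI is the total experimental time divided by the number
#' of emitted commands.
#'
#' @param bits Bits per command (from [bits_per_command()]). Vectorised.
#' @param cti_s Command transfer interval in seconds per command (> 0).
#' @return ITR in bits per minute.
#' @examples
#' itr(bits_per_command(78 / 80, 4), 128.90 / 80)
#' @export
itr <- function(bits, cti_s) {
  if (any(!is.finite(cti_s)) || any(cti_s <= 0)) abort("`cti_s` must be > 0.")
  bits * 60 / cti_s
}

#' Summarise an online session
#'
#' Aggregates per-trial decisions into the standard session report: accuracy,
#' total time, command transfer interval, bits per command, ITR and effective
#' epoch-length statistics.
#'
#' @param decisions Per-trial decision tibble from [detect_session()] (needs
#'   `correct`, `command`, `trial_s`, `epoch_s`; or at minimum `correct` and
#'   `command` with `trial_s`).
#' @param s Number of selectable targets.
#' @return A one-row tibble: `n_trials`, `n_commands`, `n_correct`,
#'   `accuracy`, `t_total_s`, `cti_s`, `bits_per_command`, `itr_bits_min`,
#'   `mean_epoch_s`, `sd_epoch_s`.
#' @export
summarize_session <- function(decisions, s = 4) {
  if (nrow(decisions) < 1L) abort("`decisions` has no trials.")
  n_commands <- sum(decisions$command)
  n_correct <- sum(decisions$correct, na.rm = TRUE)
  t_total <- sum(decisions$trial_s)
  p <- if (n_commands > 0) n_correct / n_commands else NA_real_
  cti <- if (n_commands > 0) t_total / n_commands else NA_real_
  bits <- if (n_commands > 0) bits_per_command(p, s) else NA_real_
  tibble::tibble(
    n_trials = nrow(decisions),
    n_commands = n_commands,
    n_correct = n_correct,
    accuracy = p,
    t_total_s = t_total,
    cti_s = cti,
    bits_per_command = bits,
    itr_bits_min = if (n_commands > 0) itr(bits, cti) else NA_real_,
    mean_epoch_s = mean(decisions$epoch_s),
    sd_epoch_s = sd(decisions$epoch_s)
  )
}

#' Per-class accuracies of a session
#'
#' @param decisions Per-trial decision tibble from [detect_session()].
#' @return A tibble with one row per cued class: `cue_class`, `n_trials`,
#'   `n_correct`, `accuracy`.
#' @export
per_class_accuracy <- function(decisions) {
  dplyr::summarise(
    dplyr::group_by(decisions, .data$cue_class),
    n_trials = dplyr::n(),
    n_correct = sum(.data$correct, na.rm = TRUE),
    accuracy = .data$n_correct / .data$n_trials,
    .groups = "drop"
  )
}

# ---- cycle-average phase-template baseline ---------------------------------

#' Per-interval phases of the cycle-average baseline detector
#'
#' The classical phase-only detector averages `n_cycles` consecutive
#' stimulus-locked flicker cycles (0.7 s at the default 14 cycles / 20 Hz) to
#' suppress background EEG, then reads the phase of the averaged cycle with a
#' single-cycle DFT at the flicker frequency (rectangular window -- the
#' averaging is the noise suppression, and windowing one cycle would bias the
#' phase).
#'
#' @param recording A band-pass filtered `eeg_recording` whose triggers are
#'   the reference (target 1) train.
#' @param n_cycles Cycles averaged per detection interval.
#' @param f0 Flicker frequency in Hz.
#' @return A tibble with `interval` (0-based), `start_sample`, `phase_deg`
#'   and `amplitude` per detection interval.
#' @export
cycle_average_phases <- function(recording, n_cycles = 14, f0 = 20) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording_fs(recording)
  cyc <- fs / f0
  if (abs(cyc - round(cyc)) > 1e-9) abort("fs must be a multiple of f0.")
  cyc <- as.integer(round(cyc))
  trig <- recording_triggers(recording)
  if (is.null(trig) || nrow(trig) == 0) abort("Recording has no trigger train.")
  first <- trig$onset_sample[1]
  n <- nrow(recording)
  n_avail_cycles <- (n - first) %/% cyc
  n_intervals <- n_avail_cycles %/% n_cycles
  if (n_intervals < 1) abort("Recording spans fewer than `n_cycles` cycles.")
  x <- recording$amplitude
  rot <- exp(-2i * pi * (f0 / fs) * seq_len(cyc))
  purrr::map_dfr(seq_len(n_intervals) - 1L, function(e) {
    s0 <- first + e * n_cycles * cyc
    seg <- matrix(x[(s0 + 1):(s0 + n_cycles * cyc)], nrow = cyc)
    avg <- rowMeans(seg)
    fc <- sum(avg * rot) / cyc
    tibble::tibble(interval = e, start_sample = as.integer(s0),
                   phase_deg = wrap_deg(Arg(fc) * 180 / pi),
                   amplitude = Mod(fc))
  })
}

#' Phase templates for the cycle-average baseline
#'
#' Builds one phase template per gaze class as the circular mean of the
#' cycle-average phases of that class's training recording.
#'
#' @param recordings Named list of band-pass filtered `eeg_recording`s, one
#'   per gaze class (names are the class labels).
#' @param n_cycles,f0 Passed to [cycle_average_phases()].
#' @return A named numeric vector of template phases in degrees.
#' @export
cycle_average_templates <- function(recordings, n_cycles = 14, f0 = 20) {
  vapply(recordings, function(r) {
    circ_mean_deg(cycle_average_phases(r, n_cycles, f0)$phase_deg)
  }, numeric(1))
}

#' Classify with the cycle-average phase-template baseline
#'
#' Assigns each detection interval the class whose phase template is nearest
#' in circular distance. Intervals farther than `margin` degrees from every
#' template (outside the `±45`-degree bands of the quadrature layout) are
#' flagged low-confidence but still assigned to the nearest template; exact
#' boundary ties go to the lower class index.
#'
#' @param recording A band-pass filtered `eeg_recording` to classify.
#' @param templates Named template phases from [cycle_average_templates()].
#' @param n_cycles,f0 Passed to [cycle_average_phases()].
#' @param margin Half-width of the confidence band in degrees.
#' @return The [cycle_average_phases()] tibble with `predicted` and
#'   `low_confidence` columns.
#' @export
epoch_average_baseline <- function(recording, templates, n_cycles = 14,
                                   f0 = 20, margin = 45) {
  phases <- cycle_average_phases(recording, n_cycles, f0)
  cls <- names(templates)
  dist <- vapply(cls, function(cl) {
    abs(ang_diff_deg(phases$phase_deg, templates[[cl]]))
  }, numeric(nrow(phases)))
  dist <- matrix(dist, nrow = nrow(phases), dimnames = list(NULL, cls))
  idx <- apply(dist, 1L, which.min)
  phases$predicted <- cls[idx]
  phases$low_confidence <- dist[cbind(seq_len(nrow(dist)), idx)] > margin
  phases
}
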