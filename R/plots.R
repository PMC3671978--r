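#' Plot the decision surface of a trained decoder
#'
#' Renders the amplitude-phase feature plane coloured by predicted class,
#' mirroring the standard decision-surface view: four gaze-phase bands at
#' SSVEP-level amplitudes and a low-amplitude rest region.
#'
#' @param object An `ssvep_decision_surface` from [decision_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ssvep_decision_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase_deg,
                                       y = .data$amplitude,
                                       fill = .data$predicted)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 90)) +
    ggplot2::labs(x = "Phase (deg)", y = "Amplitude (a.u.)",
                  fill = "Class",
                  title = "One-against-all SVM decision surface") +
    ggplot2::theme_minimal()
}

#' Plot per-condition phase distributions of input vectors
#'
#' Histograms of the extracted 20 Hz phases, one panel per condition: gaze
#' conditions concentrate around their phase tags (plus the common filter
#' delay and subject offset) while the resting condition is uniform over the
#' full cycle.
#'
#' @param vectors An input-vector tibble with `phase_deg` and `label`.
#' @param binwidth Histogram bin width in degrees.
#' @return A ggplot object.
#' @export
plot_phase_distribution <- function(vectors, binwidth = 10) {
  ggplot2::ggplot(vectors, ggplot2::aes(x = .data$phase_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$label)) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 360, 90)) +
    ggplot2::labs(x = "Phase (deg)", y = "Window count",
                  title = "Phase distributions at the flicker frequency") +
    ggplot2::theme_minimal()
}

#' Plot per-trial epoch lengths of an application study
#'
#' @param decisions Per-trial decisions from [detect_session()].
#' @return A ggplot object.
#' @export
plot_epoch_lengths <- function(decisions) {
  ggplot2::ggplot(decisions, ggplot2::aes(x = .data$epoch_s,
                                          fill = .data$correct)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::labs(x = "Effective epoch length (s)", y = "Trials",
                  fill = "Correct",
                  title = "Effective-epoch lengths across trials") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
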