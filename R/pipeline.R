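#' Experiment configuration
#'
#' Bundles all module settings for the end-to-end studies, with the defaults
#' of the reference protocol: 20 Hz quadrature-tagged flickers at 1 kHz,
#' 17--23 Hz 6th-order causal Butterworth band-pass, 200-sample windows with
#' 75% overlap, Z-test cleaning at 0.05, a tuned RBF one-against-all SVM, and
#' the K-S epoch gate at Z = 10 / alpha = 0.01.
#'
#' @param seed Global integer seed; all per-stage seeds derive from it.
#' @param out_dir Optional directory: when set, the studies write their
#'   artifacts (signals, events, vectors, decisions, reports) there and a
#'   manifest with file hashes is returned.
#' @param stimulus,simulation,filter,window,svm,epoch,session Named lists
#'   overriding individual fields of the respective stage defaults.
#' @param yaml_file Optional path to a YAML file whose top-level sections
#'   (same names as the list arguments, plus `seed`/`out_dir`) override the
#'   defaults; explicit arguments override the file.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, out_dir = NULL,
                              stimulus = list(), simulation = list(),
                              filter = list(), window = list(),
                              svm = list(), epoch = list(),
                              session = list(), yaml_file = NULL) {
  defaults <- list(
    seed = as.integer(seed), out_dir = out_dir,
    stimulus = list(f0 = 20, fs = 1000, phases = c(0, 90, 180, 270)),
    simulation = list(ssvep_amplitude = 1.0, subject_phase_offset = NULL,
                      noise_sd = 1.25, noise_band = c(0.1, 100),
                      phase_jitter_sd = 0, one_over_f = FALSE),
    filter = list(band = c(17, 23), order = 6),
    window = list(k = 200, overlap = 0.75),
    svm = list(alpha = 0.05, tune = TRUE, cost = 10, gamma = 0.5,
               encoding = "amplitude_phase"),
    epoch = list(z = 10, alpha = 0.01, max_vectors = 597,
                 transition_exclude = 10),
    session = list(n_trials_per_class = 20, gaze_s = 4, transition_s = 0.5,
                   record_s = 60)
  )
  if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    for (sec in intersect(names(y), names(defaults))) {
      if (is.list(defaults[[sec]])) {
        defaults[[sec]][names(y[[sec]])] <- y[[sec]]
      } else {
        defaults[[sec]] <- y[[sec]]
      }
    }
  }
  overrides <- list(stimulus = stimulus, simulation = simulation,
                    filter = filter, window = window, svm = svm,
                    epoch = epoch, session = session)
  for (sec in names(overrides)) {
    unknown <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
    if (length(unknown)) {
      abort(sprintf("Unknown `%s` setting(s): %s", sec,
                    paste(unknown, collapse = ", ")))
    }
    defaults[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
  }
  structure(defaults, class = "experiment_config")
}

config_objects <- function(config) {
  st <- config$stimulus
  si <- config$simulation
  list(
    config = stimulus_config(f0 = st$f0, fs = st$fs, phases = st$phases),
    params = sim_params(ssvep_amplitude = si$ssvep_amplitude,
                        subject_phase_offset = si$subject_phase_offset,
                        noise_sd = si$noise_sd, noise_band = si$noise_band,
                        phase_jitter_sd = si$phase_jitter_sd,
                        one_over_f = si$one_over_f, seed = config$seed)
  )
}

write_artifact <- function(writer, obj, out_dir, name, manifest) {
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, name)
  writer(obj, path)
  dplyr::bind_rows(manifest, tibble::tibble(
    file = name, md5 = unname(tools::md5sum(path))
  ))
}

#' Run the offline classification study
#'
#' The calibration experiment of the protocol: record 60 s per condition
#' (each of the `S` gaze targets plus eyes-open rest), band-pass filter,
#' extract input vectors, use the first-half vectors (30 s, 597 per
#' condition at the defaults) -- Z-test cleaned -- to train the
#' one-against-all SVM, and evaluate on the held-out second halves. The
#' held-out gaze halves are consumed the way the online system would consume
#' them: segmented into voted effective epochs ([segment_epochs()]), one
#' decision per epoch. The 14-cycle epoch-average baseline is calibrated on
#' the training halves and evaluated on the same held-out gaze data for
#' comparison at a matched decision horizon.
#'
#' @param config An [experiment_config()].
#' @return A list of class `classification_study`: `model`, `accuracy`
#'   (held-out epoch-level), `vector_accuracy` (per-vector diagnostic over
#'   all five conditions), `mean_epoch_s`, `per_class`, `epoch_results`,
#'   `test_results` (per-vector predictions), `baseline_accuracy`,
#'   `baseline_results`, `n_train_raw`, `n_train_clean`, `exclusions`,
#'   `manifest`.
#' @export
run_classification_study <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  obj <- config_objects(config)
  scfg <- obj$config
  params <- obj$params
  fs <- scfg$fs
  record_s <- config$session$record_s
  half_n <- round(record_s / 2 * fs)
  conditions <- c(as.character(seq_len(scfg$n_targets)), "rest")
  manifest <- tibble::tibble(file = character(), md5 = character())

  half_recording <- function(filtered, idx, condition, duration_s) {
    rec <- new_recording(filtered$amplitude[idx], fs, condition,
                         generate_triggers(scfg, 1L, duration_s))
    rec
  }

  train_vecs <- list(); test_vecs <- list()
  train_recs <- list(); test_recs <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    rec <- simulate_recording(cond, record_s, params, scfg,
                              seed = config$seed * 1000L + i)
    manifest <- write_artifact(write_signal, rec, config$out_dir,
                               sprintf("signal_%s.tsv", cond), manifest)
    filtered <- bandpass(rec, band = config$filter$band,
                         order = config$filter$order)
    tr <- half_recording(filtered, seq_len(half_n), cond, record_s / 2)
    te <- half_recording(filtered, half_n + seq_len(half_n), cond, record_s / 2)
    train_vecs[[cond]] <- vectors_from_recording(
      tr, k = config$window$k, overlap = config$window$overlap, f0 = scfg$f0)
    test_vecs[[cond]] <- vectors_from_recording(
      te, k = config$window$k, overlap = config$window$overlap, f0 = scfg$f0)
    if (cond != "rest") {
      train_recs[[cond]] <- tr
      test_recs[[cond]] <- te
    }
  }
  training <- dplyr::bind_rows(train_vecs)
  testing <- dplyr::bind_rows(test_vecs)
  manifest <- write_artifact(write_vectors, training, config$out_dir,
                             "train_vectors.tsv", manifest)

  cleaned <- z_test_clean(training, alpha = config$svm$alpha)
  model <- svm_train(cleaned, cost = config$svm$cost, gamma = config$svm$gamma,
                     tune = config$svm$tune, encoding = config$svm$encoding,
                     seed = config$seed)

  test_results <- classify_vectors(testing, model)
  vector_accuracy <- mean(test_results$predicted == test_results$label)

  # held-out evaluation the way the online system consumes data: segment each
  # gaze test half into voted effective epochs, one decision per epoch
  step <- as.integer(round(config$window$k * (1 - config$window$overlap)))
  policy <- epoch_policy(z = config$epoch$z, alpha = config$epoch$alpha,
                         max_vectors = config$epoch$max_vectors)
  epoch_results <- purrr::map_dfr(
    as.character(seq_len(scfg$n_targets)),
    function(cond) segment_epochs(test_vecs[[cond]], model, policy,
                                  k = config$window$k, step = step, fs = fs)
  )
  emitted <- dplyr::filter(epoch_results, .data$status == "epoch")
  accuracy <- mean(emitted$predicted == emitted$label)
  per_class <- dplyr::summarise(
    dplyr::group_by(emitted, .data$label),
    n = dplyr::n(),
    n_correct = sum(.data$predicted == .data$label),
    accuracy = .data$n_correct / .data$n,
    mean_epoch_s = mean(.data$epoch_s),
    .groups = "drop"
  )

  templates <- cycle_average_templates(train_recs, f0 = scfg$f0)
  baseline_results <- purrr::imap_dfr(test_recs, function(rec, cond) {
    res <- epoch_average_baseline(rec, templates, f0 = scfg$f0)
    res$label <- cond
    res
  })
  baseline_accuracy <- mean(baseline_results$predicted ==
                              baseline_results$label)

  out <- structure(
    list(model = model, test_results = test_results,
         epoch_results = epoch_results, accuracy = accuracy,
         vector_accuracy = vector_accuracy,
         mean_epoch_s = mean(emitted$epoch_s),
         per_class = per_class, baseline_accuracy = baseline_accuracy,
         baseline_results = baseline_results,
         n_train_raw = nrow(training), n_train_clean = nrow(cleaned),
         exclusions = attr(cleaned, "exclusion_log"),
         seed = config$seed, manifest = manifest),
    class = "classification_study"
  )
  if (!is.null(config$out_dir)) {
    report <- glance(out)
    readr::write_tsv(report, file.path(config$out_dir,
                                       "classification_report.tsv"),
                     progress = FALSE)
  }
  out
}

#' @export
print.classification_study <- function(x, ...) {
  cat(sprintf(
    paste0("<classification_study> held-out epoch accuracy %.2f%% ",
           "(mean epoch %.2f s; baseline %.2f%%; per-vector %.2f%%), ",
           "%d/%d training vectors retained\n"),
    100 * x$accuracy, x$mean_epoch_s, 100 * x$baseline_accuracy,
    100 * x$vector_accuracy, x$n_train_clean, x$n_train_raw
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.classification_study <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    vector_accuracy = x$vector_accuracy,
    baseline_accuracy = x$baseline_accuracy,
    mean_epoch_s = x$mean_epoch_s,
    n_epochs = sum(x$epoch_results$status == "epoch"),
    n_train_raw = x$n_train_raw,
    n_train_clean = x$n_train_clean,
    n_test = nrow(x$test_results),
    seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.classification_study <- function(x, ...) x$per_class

#' Run the online application study
#'
#' The online experiment of the protocol: `S * n_trials_per_class` cued
#' trials in randomized order. Each trial's post-transition vector stream is
#' grown into an effective epoch by the K-S gate, classified vector-by-vector
#' by the trained SVM, and reduced to one command by plurality voting. The
#' session is summarised Wolpaw-style (accuracy, CTI, bits/command, ITR).
#'
#' @param config An [experiment_config()].
#' @param model A trained `ssvep_svm`; when `NULL`, [run_classification_study()]
#'   is run first with the same config and its model is used.
#' @return A list of class `application_study`: `decisions` (per-trial
#'   tibble), `summary` (one-row tibble), `per_class`, `model`, `manifest`.
#' @export
run_application_study <- function(config = experiment_config(), model = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(model)) {
    model <- run_classification_study(config)$model
  }
  stopifnot(inherits(model, "ssvep_svm"))
  obj <- config_objects(config)
  manifest <- tibble::tibble(file = character(), md5 = character())

  session <- simulate_online_session(
    obj$params, obj$config,
    n_trials_per_class = config$session$n_trials_per_class,
    gaze_s = config$session$gaze_s,
    transition_s = config$session$transition_s,
    seed = config$seed * 1000L + 99L
  )
  manifest <- write_artifact(write_signal, session$recording, config$out_dir,
                             "session_signal.tsv", manifest)
  vecs <- vectors_from_session(
    session, band = config$filter$band, order = config$filter$order,
    k = config$window$k, overlap = config$window$overlap, f0 = obj$config$f0,
    transition_exclude = config$epoch$transition_exclude
  )
  step <- as.integer(round(config$window$k * (1 - config$window$overlap)))
  policy <- epoch_policy(z = config$epoch$z, alpha = config$epoch$alpha,
                         max_vectors = config$epoch$max_vectors)
  decisions <- detect_session(vecs, model, policy,
                              transition_s = session$transition_s,
                              k = config$window$k, step = step,
                              fs = obj$config$fs)
  summary <- summarize_session(decisions, s = obj$config$n_targets)
  manifest <- write_artifact(
    function(d, p) readr::write_tsv(d, p, progress = FALSE),
    decisions, config$out_dir, "decisions.tsv", manifest)
  if (!is.null(config$out_dir)) {
    readr::write_tsv(summary, file.path(config$out_dir,
                                        "application_report.tsv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(summary),
                         file.path(config$out_dir, "application_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(
    list(decisions = decisions, summary = summary,
         per_class = per_class_accuracy(decisions), model = model,
         seed = config$seed, manifest = manifest),
    class = "application_study"
  )
}

#' @export
print.application_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<application_study> %d trials, accuracy %.2f%%, mean epoch %.2f s, ITR %.2f bits/min\n",
    s$n_trials, 100 * s$accuracy, s$mean_epoch_s, s$itr_bits_min
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.application_study <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.application_study <- function(x, ...) x$decisions
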