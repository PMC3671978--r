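# Columnar text formats: a signal file (sample_index, amplitude_uV) with a
# '# key=value' header, an event file (sample_index, led_index) and a vector
# file. Chosen over binary for diffability; numerics round-trip at full
# precision (%.17g).

fmt_full <- function(x) sprintf("%.17g", x)

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- strsplit(kv, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort("Malformed '# key=value' header line in signal file.")
  setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
}

#' Read and write signal files
#'
#' A signal file stores one EEG recording as tab-separated
#' `sample_index` / `amplitude_uV` columns preceded by `# key=value` header
#' lines carrying at least `fs` (Hz) and optionally `condition`.
#'
#' @param recording An `eeg_recording`.
#' @param path File path.
#' @return `read_signal()` returns an `eeg_recording` (without triggers; see
#'   [read_events()]); `write_signal()` returns `path` invisibly.
#' @export
write_signal <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  header <- c(
    sprintf("# fs=%s", fmt_full(recording_fs(recording))),
    sprintf("# units=uV"),
    sprintf("# condition=%s", recording_condition(recording))
  )
  body <- sprintf("%d\t%s", recording$sample, fmt_full(recording$amplitude))
  writeLines(c(header, "sample_index\tamplitude_uV", body), path)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- parse_header(lines[is_hdr])
  if (!"fs" %in% names(meta)) abort("Signal file header lacks 'fs'.")
  body <- lines[!is_hdr]
  if (length(body) < 1L || !identical(body[1], "sample_index\tamplitude_uV")) {
    abort("Signal file lacks the 'sample_index\tamplitude_uV' header row.")
  }
  # parse doubles with base strtod (correctly rounded) so that %.17g output
  # round-trips bit-exactly
  df <- readr::read_tsv(I(body), col_types = readr::cols(
    sample_index = readr::col_integer(), amplitude_uV = readr::col_character()
  ), progress = FALSE)
  df$amplitude_uV <- as.numeric(df$amplitude_uV)
  if (anyNA(df$amplitude_uV)) abort("Signal file contains NA samples.")
  new_recording(df$amplitude_uV, as.numeric(meta[["fs"]]),
                if ("condition" %in% names(meta)) meta[["condition"]] else NA,
                NULL)
}

#' Read and write event files
#'
#' An event file stores flash-onset trigger events as tab-separated
#' `sample_index` / `led_index` columns with a header row. Onsets must be
#' strictly increasing within each LED.
#'
#' @param triggers A `trigger_train` tibble (columns `led`, `onset_sample`).
#' @param path File path.
#' @return `read_events()` returns a `trigger_train` tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(triggers, path) {
  stopifnot(all(c("led", "onset_sample") %in% names(triggers)))
  writeLines(c("sample_index\tled_index",
               sprintf("%d\t%d", triggers$onset_sample, triggers$led)), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_index = readr::col_integer(), led_index = readr::col_integer()
  ), progress = FALSE)
  if (!all(c("sample_index", "led_index") %in% names(df))) {
    abort("Event file must have 'sample_index' and 'led_index' columns.")
  }
  if (anyNA(df)) abort("Event file contains NA entries.")
  out <- tibble::tibble(led = df$led_index, onset_sample = df$sample_index)
  bad <- dplyr::summarise(dplyr::group_by(out, .data$led),
                          ok = !is.unsorted(.data$onset_sample, strictly = TRUE))
  if (any(!bad$ok)) abort("Event onsets must be strictly increasing per LED.")
  class(out) <- c("trigger_train", class(out))
  out
}

#' Read and write input-vector files
#'
#' Tab-separated text with columns `window_index`, `start_sample`,
#' `amplitude`, `phase_deg` and optionally `label`, `trial`, `cue_class`.
#' Numeric columns round-trip at full precision.
#'
#' @param vectors An input-vector tibble.
#' @param path File path.
#' @return `read_vectors()` returns a tibble; `write_vectors()` returns
#'   `path` invisibly.
#' @export
write_vectors <- function(vectors, path) {
  out <- vectors
  for (col in intersect(c("amplitude", "phase_deg"), names(out))) {
    out[[col]] <- fmt_full(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_vectors
#' @export
read_vectors <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    window_index = readr::col_integer(),
    start_sample = readr::col_integer(),
    amplitude = readr::col_character(),
    phase_deg = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  df$amplitude <- as.numeric(df$amplitude)
  df$phase_deg <- as.numeric(df$phase_deg)
  if (anyNA(df$amplitude) || anyNA(df$phase_deg)) {
    abort("Vector file contains NA features.")
  }
  if ("label" %in% names(df)) df$label <- as.character(df$label)
  if ("cue_class" %in% names(df)) df$cue_class <- as.character(df$cue_class)
  df
}
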