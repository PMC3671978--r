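#' Effective-epoch detection policy
#'
#' Online command output is gated on statistical evidence of gaze: an epoch
#' of input vectors is grown one vector at a time until its phase set rejects
#' uniformity by a one-sample Kolmogorov-Smirnov test, at which point it is
#' declared an effective epoch and voted on.
#'
#' @param z Initial epoch length in input vectors (default 10, i.e. 0.65 s at
#'   the default window settings).
#' @param alpha K-S significance level (default 0.01).
#' @param max_vectors Timeout cap on the epoch length (default 597, about
#'   30 s of stream; the protocol itself sets no cap, but an online system
#'   must terminate).
#' @return An object of class `epoch_policy`.
#' @export
epoch_policy <- function(z = 10, alpha = 0.01, max_vectors = 597) {
  if (z < 2 || z != round(z)) abort("`z` must be an integer >= 2.")
  stopifnot_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (max_vectors < z) abort("`max_vectors` must be >= `z`.")
  structure(list(z = as.integer(z), alpha = alpha,
                 max_vectors = as.integer(max_vectors)),
            class = "epoch_policy")
}

#' One-sample Kolmogorov-Smirnov test against uniform phase
#'
#' Tests whether a set of phases is compatible with the uniform distribution
#' on `[0, 360)` -- the null model for resting-state (non-gaze) EEG phase at
#' the flicker frequency. The statistic is `D = sup |ECDF - U(0, 360) CDF|`;
#' the p-value comes from the exact small-sample Kolmogorov distribution for
#' `n <= 100` (epoch sizes live there) and the asymptotic series beyond.
#'
#' @param phases Numeric phases in degrees, in `[0, 360)`.
#' @return The p-value, with the K-S statistic attached as attribute
#'   `"statistic"`.
#' @examples
#' ks_uniform_pvalue(rep(90, 10)) # concentrated: tiny p
#' @export
ks_uniform_pvalue <- function(phases) {
  if (length(phases) < 1L || anyNA(phases)) {
    abort("`phases` must be a non-empty numeric vector without NA.")
  }
  if (any(phases < 0 | phases >= 360)) abort("`phases` must lie in [0, 360).")
  # identical phases are legitimate here (a noiseless stream); the continuity
  # warning ks.test emits for ties does not invalidate D, so silence it
  res <- suppressWarnings(
    ks.test(phases, "punif", min = 0, max = 360,
            exact = length(phases) <= 100)
  )
  structure(unname(res$p.value), statistic = unname(res$statistic))
}

#' Grow an effective epoch from an ordered vector stream
#'
#' Starts with the first `z` vectors of the stream and repeatedly appends one
#' vector while the phase set fails to reject uniformity
#' (`p > alpha`). The first prefix whose phases reject uniformity is returned
#' as the effective epoch; a stream shorter than `z` gives a `"no_decision"`
#' marker, and reaching `max_vectors` without rejection gives `"timeout"`.
#'
#' @param stream A tibble of input vectors (ordered; needs `phase_deg`).
#' @param policy An [epoch_policy()].
#' @param k,step Window length and step in samples, used only to express the
#'   epoch span in seconds (first window start to last window end).
#' @param fs Sampling rate in Hz.
#' @return An object of class `effective_epoch`: list with `status` (one of
#'   `"epoch"`, `"timeout"`, `"no_decision"`), `vectors` (the consumed
#'   prefix), `n_vectors`, `ks_p` and `epoch_s`.
#' @export
detect_effective_epoch <- function(stream, policy = epoch_policy(),
                                   k = 200, step = 50, fs = 1000) {
  stopifnot(inherits(policy, "epoch_policy"))
  n_avail <- nrow(stream)
  if (n_avail < policy$z) {
    return(structure(
      list(status = "no_decision", vectors = stream,
           n_vectors = n_avail, ks_p = NA_real_,
           epoch_s = epoch_seconds(n_avail, k, step, fs)),
      class = "effective_epoch"
    ))
  }
  n_max <- min(n_avail, policy$max_vectors)
  n <- policy$z
  repeat {
    p <- ks_uniform_pvalue(stream$phase_deg[seq_len(n)])
    if (p <= policy$alpha) {
      return(structure(
        list(status = "epoch", vectors = stream[seq_len(n), ],
             n_vectors = n, ks_p = as.numeric(p),
             epoch_s = epoch_seconds(n, k, step, fs)),
        class = "effective_epoch"
      ))
    }
    if (n >= n_max) {
      return(structure(
        list(status = "timeout", vectors = stream[seq_len(n), ],
             n_vectors = n, ks_p = as.numeric(p),
             epoch_s = epoch_seconds(n, k, step, fs)),
        class = "effective_epoch"
      ))
    }
    n <- n + 1L
  }
}

# Span from the first window's start to the last window's end.
epoch_seconds <- function(n_vectors, k, step, fs) {
  if (n_vectors < 1) return(0)
  (k + (n_vectors - 1) * step) / fs
}

#' @export
print.effective_epoch <- function(x, ...) {
  cat(sprintf("<effective_epoch> status = %s, %d vectors (%.2f s), K-S p = %s\n",
              x$status, x$n_vectors, x$epoch_s, format(x$ks_p)))
  invisible(x)
}

#' Plurality vote over an epoch's per-vector classifications
#'
#' Each input vector of an effective epoch casts one vote (its SVM class);
#' the modal class wins. Vote ties are broken toward the tied class with the
#' largest decision-value sum over the epoch (the tie is flagged in the
#' `"tie"` attribute). A `"rest"` winner means the epoch carries no gaze
#' command; the session layer maps it to "no command".
#'
#' @param votes Character vector of per-vector predicted classes.
#' @param decision_values Optional numeric matrix (vectors x classes, named
#'   columns) used for tie-breaking.
#' @return The winning class (length-1 character) with attribute `"tie"`.
#' @export
plurality_vote <- function(votes, decision_values = NULL) {
  if (length(votes) < 1L) abort("`votes` must be non-empty.")
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  tie <- length(winners) > 1L
  if (tie && !is.null(decision_values)) {
    sums <- colSums(decision_values[, winners, drop = FALSE])
    winners <- winners[which.max(sums)]
  }
  structure(winners[1L], tie = tie)
}

#' Run effective-epoch detection and voting over an online session
#'
#' The online decoding loop: for every trial, take the post-transition vector
#' stream, grow the effective epoch ([detect_effective_epoch()]), classify
#' its vectors ([classify_vectors()]) and emit one command by plurality vote.
#' Trial time is the transition span plus the epoch span; a `"rest"` vote or
#' a timeout emits no command.
#'
#' @param session_vectors Per-trial input vectors from
#'   [vectors_from_session()].
#' @param model A trained `ssvep_svm`.
#' @param policy An [epoch_policy()].
#' @param transition_s Transition span charged to every trial, in seconds.
#' @param k,step,fs Window geometry (samples, samples, Hz).
#' @return A tibble of per-trial decisions: `trial`, `cue_class`,
#'   `predicted` (`NA` when no command was emitted), `command` (logical),
#'   `correct`, `n_vectors`, `epoch_s`, `ks_p`, `status`, `trial_s`.
#' @export
detect_session <- function(session_vectors, model, policy = epoch_policy(),
                           transition_s = 0.5, k = 200, step = 50, fs = 1000) {
  stopifnot(inherits(model, "ssvep_svm"))
  dv_cols <- paste0("dv_", model$classes)
  res <- dplyr::group_modify(
    dplyr::group_by(session_vectors, .data$trial, .data$cue_class),
    function(d, key) {
      ep <- detect_effective_epoch(d, policy, k = k, step = step, fs = fs)
      if (ep$status == "epoch") {
        cls <- classify_vectors(ep$vectors, model)
        dv <- as.matrix(cls[dv_cols])
        colnames(dv) <- model$classes
        vote <- plurality_vote(cls$predicted, dv)
        predicted <- as.character(vote)
      } else {
        predicted <- NA_character_
      }
      command <- !is.na(predicted) && predicted != "rest"
      tibble::tibble(
        predicted = if (command) predicted else NA_character_,
        command = command,
        n_vectors = ep$n_vectors,
        epoch_s = ep$epoch_s,
        ks_p = ep$ks_p,
        status = ep$status,
        trial_s = transition_s + ep$epoch_s
      )
    }
  )
  res <- dplyr::ungroup(res)
  dplyr::mutate(res, correct = .data$command & .data$predicted == .data$cue_class,
                .after = "predicted")
}

#' Segment a continuous vector stream into voted effective epochs
#'
#' Offline analogue of the online loop: starting at the head of the stream,
#' grow an effective epoch, classify its vectors and emit one plurality vote,
#' then reset the accumulator and continue from the next unconsumed vector
#' until the stream is exhausted. Used to evaluate a trained decoder on a
#' held-out continuous recording the way the online system would consume it.
#'
#' @param stream A tibble of ordered input vectors (needs `phase_deg`,
#'   `amplitude`; a `label` column, if present, is carried through).
#' @param model A trained `ssvep_svm`.
#' @param policy An [epoch_policy()].
#' @param k,step,fs Window geometry (samples, samples, Hz).
#' @return A tibble with one row per emitted epoch: `epoch_index`,
#'   `predicted`, `n_vectors`, `epoch_s`, `ks_p`, `status` and (when the
#'   stream is labelled) `label`.
#' @export
segment_epochs <- function(stream, model, policy = epoch_policy(),
                           k = 200, step = 50, fs = 1000) {
  stopifnot(inherits(model, "ssvep_svm"))
  dv_cols <- paste0("dv_", model$classes)
  out <- list()
  pos <- 0L
  idx <- 0L
  n <- nrow(stream)
  while (n - pos >= policy$z) {
    ep <- detect_effective_epoch(stream[(pos + 1L):n, ], policy,
                                 k = k, step = step, fs = fs)
    predicted <- NA_character_
    if (ep$status == "epoch") {
      cls <- classify_vectors(ep$vectors, model)
      dv <- as.matrix(cls[dv_cols])
      colnames(dv) <- model$classes
      predicted <- as.character(plurality_vote(cls$predicted, dv))
    }
    idx <- idx + 1L
    out[[idx]] <- tibble::tibble(
      epoch_index = idx,
      label = if ("label" %in% names(stream)) stream$label[pos + 1L] else NA_character_,
      predicted = predicted,
      n_vectors = ep$n_vectors,
      epoch_s = ep$epoch_s,
      ks_p = ep$ks_p,
      status = ep$status
    )
    pos <- pos + ep$n_vectors
    if (ep$status != "epoch") break
  }
  dplyr::bind_rows(out)
}
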