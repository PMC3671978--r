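#' Z-test cleaning of training vectors
#'
#' Screens the training vectors of each gaze class for statistical outliers
#' before SVM training. Within each gaze class, a vector is excluded when a
#' two-sided Z-test at level `alpha` rejects for either feature: the
#' amplitude z-score against the class mean and SD, or the angular deviation
#' from the class circular mean scaled by the class circular SD. Resting-state
#' vectors are left untouched. A class feature with zero spread is skipped
#' with a warning.
#'
#' @param vectors A tibble with columns `amplitude`, `phase_deg` and `label`
#'   (gaze classes plus optionally `"rest"`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The retained vectors. The exclusions, with their z-scores and the
#'   feature that triggered removal, are attached as the `"exclusion_log"`
#'   attribute (also a tibble).
#' @export
z_test_clean <- function(vectors, alpha = 0.05) {
  stopifnot(all(c("amplitude", "phase_deg", "label") %in% names(vectors)))
  stopifnot_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)

  vectors <- dplyr::mutate(vectors, .row_id = dplyr::row_number())
  gaze <- dplyr::filter(vectors, .data$label != "rest")
  rest <- dplyr::filter(vectors, .data$label == "rest")
  if (nrow(gaze) == 0L) {
    out <- dplyr::select(vectors, -".row_id")
    attr(out, "exclusion_log") <- tibble::tibble(
      label = character(), z_amplitude = numeric(), z_phase = numeric(),
      reason = character()
    )
    return(out)
  }

  scored <- dplyr::group_modify(dplyr::group_by(gaze, .data$label), function(d, key) {
    mu_a <- mean(d$amplitude)
    sd_a <- sd(d$amplitude)
    if (is.na(sd_a) || sd_a == 0) {
      warn(sprintf("Class %s: zero amplitude SD; amplitude Z-test skipped.", key$label))
      z_a <- rep(0, nrow(d))
    } else {
      z_a <- (d$amplitude - mu_a) / sd_a
    }
    mu_p <- circ_mean_deg(d$phase_deg)
    sd_p <- circ_sd_deg(d$phase_deg)
    if (!is.finite(sd_p) || sd_p == 0) {
      warn(sprintf("Class %s: zero phase spread; phase Z-test skipped.", key$label))
      z_p <- rep(0, nrow(d))
    } else {
      z_p <- ang_diff_deg(d$phase_deg, mu_p) / sd_p
    }
    d$z_amplitude <- z_a
    d$z_phase <- z_p
    d
  })
  scored <- dplyr::ungroup(scored)
  crit <- stats::qnorm(1 - alpha / 2)
  scored <- dplyr::mutate(
    scored,
    excluded = abs(.data$z_amplitude) > crit | abs(.data$z_phase) > crit,
    reason = dplyr::case_when(
      abs(.data$z_amplitude) > crit & abs(.data$z_phase) > crit ~ "both",
      abs(.data$z_amplitude) > crit ~ "amplitude",
      abs(.data$z_phase) > crit ~ "phase",
      TRUE ~ NA_character_
    )
  )
  log <- dplyr::select(
    dplyr::filter(scored, .data$excluded),
    "label", "z_amplitude", "z_phase", "reason",
    dplyr::any_of(c("window_index", "start_sample"))
  )
  kept_ids <- c(scored$.row_id[!scored$excluded], rest$.row_id)
  out <- dplyr::arrange(
    dplyr::filter(vectors, .data$.row_id %in% kept_ids), .data$.row_id
  )
  out$.row_id <- NULL
  attr(out, "exclusion_log") <- log
  out
}

# e1071 orients decision values by the order in which labels appear in the
# training data, not by factor levels: normalise so positive always means
# "this class".
binary_decision_values <- function(machine, x) {
  d <- attr(stats::predict(machine, x, decision.values = TRUE), "decision.values")
  if (colnames(d)[1] == "other/target") -d[, 1] else d[, 1]
}

feature_matrix <- function(vectors, encoding) {
  if (encoding == "amplitude_phase") {
    cbind(amplitude = vectors$amplitude, phase_deg = vectors$phase_deg)
  } else {
    rad <- vectors$phase_deg * pi / 180
    cbind(re = vectors$amplitude * cos(rad), im = vectors$amplitude * sin(rad))
  }
}

#' Train the one-against-all multiclass SVM
#'
#' Fits one binary RBF-kernel support vector machine per class (each class
#' against all others) on the 2-D `(amplitude, phase)` feature plane;
#' classification takes the class whose binary machine yields the maximum
#' decision value. Features are standardised with training-set statistics
#' (the default scaling of the underlying binary machines). With
#' `tune = TRUE`, `cost` and `gamma` are selected by cross-validated grid
#' search on the multiclass accuracy.
#'
#' @param vectors A training tibble with `amplitude`, `phase_deg` and `label`
#'   columns; at least two classes must be present. For the full decoder the
#'   labels are the `S` gaze classes plus `"rest"`.
#' @param cost,gamma RBF hyperparameters used when `tune = FALSE` (and as
#'   fallback defaults).
#' @param tune If `TRUE` (default), select `cost` and `gamma` from
#'   `tune_grid` by `tune_folds`-fold cross-validation.
#' @param tune_grid Named list with numeric `cost` and `gamma` candidates.
#' @param tune_folds Number of cross-validation folds.
#' @param encoding `"amplitude_phase"` feeds the raw 2-D vector (default);
#'   `"cartesian"` feeds `(amplitude cos phase, amplitude sin phase)`, which
#'   removes the 0/360 phase seam.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `ssvep_svm` holding the per-class binary
#'   machines and training metadata. Use [classify_vectors()] or
#'   `predict()` to classify, [tidy()] / [glance()] to inspect.
#' @export
svm_train <- function(vectors, cost = 10, gamma = 0.5, tune = TRUE,
                      tune_grid = list(cost = c(1, 10, 100),
                                       gamma = c(0.05, 0.5)),
                      tune_folds = 3, encoding = c("amplitude_phase", "cartesian"),
                      seed = 1L) {
  stopifnot(all(c("amplitude", "phase_deg", "label") %in% names(vectors)))
  encoding <- match.arg(encoding)
  classes <- unique(vectors$label)
  gaze_classes <- setdiff(classes, "rest")
  num <- suppressWarnings(as.integer(gaze_classes))
  gaze_classes <- if (anyNA(num)) sort(gaze_classes) else as.character(sort(num))
  classes <- c(gaze_classes, if ("rest" %in% classes) "rest")
  if (length(classes) < 2L) {
    abort(sprintf("Training needs >= 2 classes; got only class %s.",
                  paste(classes, collapse = ", ")))
  }
  x <- feature_matrix(vectors, encoding)
  y <- vectors$label

  cv_table <- NULL
  if (tune) {
    grid <- expand.grid(cost = tune_grid$cost, gamma = tune_grid$gamma)
    folds <- with_seed_if(seed, sample(rep_len(seq_len(tune_folds), nrow(x))))
    grid$accuracy <- purrr::map2_dbl(grid$cost, grid$gamma, function(cc, gg) {
      accs <- purrr::map_dbl(seq_len(tune_folds), function(f) {
        tr <- folds != f
        machines <- fit_binary_machines(x[tr, , drop = FALSE], y[tr],
                                        classes, cc, gg)
        pred <- argmax_classify(machines, classes, x[!tr, , drop = FALSE])$class
        mean(pred == y[!tr])
      })
      mean(accs)
    })
    best <- grid[which.max(grid$accuracy), ]
    cost <- best$cost
    gamma <- best$gamma
    cv_table <- tibble::as_tibble(grid)
  }

  machines <- fit_binary_machines(x, y, classes, cost, gamma)
  structure(
    list(machines = machines, classes = classes, encoding = encoding,
         cost = cost, gamma = gamma, cv = cv_table, n_train = nrow(x),
         seed = as.integer(seed)),
    class = "ssvep_svm"
  )
}

fit_binary_machines <- function(x, y, classes, cost, gamma) {
  setNames(lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "target", "other"),
                 levels = c("target", "other"))
    e1071::svm(x, yy, kernel = "radial", cost = cost, gamma = gamma,
               scale = TRUE)
  }), classes)
}

argmax_classify <- function(machines, classes, x) {
  dv <- vapply(classes, function(cl) binary_decision_values(machines[[cl]], x),
               numeric(nrow(x)))
  dv <- matrix(dv, nrow = nrow(x), dimnames = list(NULL, classes))
  # which.max returns the first maximum: ties resolve to the lower class index
  idx <- apply(dv, 1L, which.max)
  list(class = classes[idx], decision_values = dv)
}

#' Classify input vectors with a trained model
#'
#' Evaluates all binary machines on each vector and assigns the class with
#' the maximum decision value (ties go to the lower class index, `"rest"`
#' last).
#'
#' @param vectors A tibble with `amplitude` and `phase_deg` columns.
#' @param model An `ssvep_svm` from [svm_train()].
#' @return The input tibble with a `predicted` column and one
#'   `dv_<class>` column of decision values per class.
#' @export
classify_vectors <- function(vectors, model) {
  stopifnot(inherits(model, "ssvep_svm"))
  x <- feature_matrix(vectors, model$encoding)
  res <- argmax_classify(model$machines, model$classes, x)
  out <- vectors
  out$predicted <- res$class
  dv <- tibble::as_tibble(res$decision_values, .name_repair = "minimal")
  names(dv) <- paste0("dv_", model$classes)
  dplyr::bind_cols(out, dv)
}

#' @export
#' @param object An `ssvep_svm`.
#' @param newdata A tibble with `amplitude` and `phase_deg` columns.
#' @param ... Unused.
#' @rdname classify_vectors
predict.ssvep_svm <- function(object, newdata, ...) {
  classify_vectors(newdata, object)$predicted
}

#' @export
print.ssvep_svm <- function(x, ...) {
  cat(sprintf(
    "<ssvep_svm> %d one-against-all machines (%s), RBF cost = %g, gamma = %g, n_train = %d\n",
    length(x$classes), paste(x$classes, collapse = "/"), x$cost, x$gamma,
    x$n_train
  ))
  invisible(x)
}

#' Broom-style summaries of a trained decoder
#'
#' `tidy()` returns one row per binary machine (class, support-vector count);
#' `glance()` returns a one-row model summary.
#'
#' @param x An `ssvep_svm`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ssvep_svm <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    n_support_vectors = purrr::map_int(x$machines[x$classes],
                                       ~ .x$tot.nSV),
    cost = x$cost,
    gamma = x$gamma
  )
}

#' @rdname tidy.ssvep_svm
#' @exportS3Method generics::glance
glance.ssvep_svm <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_train = x$n_train,
    cost = x$cost,
    gamma = x$gamma,
    encoding = x$encoding,
    tuned = !is.null(x$cv)
  )
}

#' Decision surface of the trained decoder
#'
#' Evaluates the classifier over a regular grid of the feature plane, giving
#' the label partition and the winning decision value at every node --
#' useful for visualising how the machines carve amplitude-phase space into
#' the four gaze classes and the low-amplitude rest region.
#'
#' @param model An `ssvep_svm`.
#' @param amplitude_range,phase_range Length-2 numeric ranges.
#' @param grid_n Nodes per axis (>= 2).
#' @return A tibble of class `ssvep_decision_surface` with columns
#'   `amplitude`, `phase_deg`, `predicted` and `decision_value` (`grid_n^2`
#'   rows).
#' @export
decision_surface <- function(model, amplitude_range, phase_range = c(0, 360),
                             grid_n = 101) {
  stopifnot(inherits(model, "ssvep_svm"))
  if (grid_n < 2) abort("`grid_n` must be >= 2.")
  if (diff(amplitude_range) <= 0 || diff(phase_range) <= 0) {
    abort("Grid ranges must be increasing.")
  }
  grid <- tidyr::expand_grid(
    amplitude = seq(amplitude_range[1], amplitude_range[2], length.out = grid_n),
    phase_deg = seq(phase_range[1], phase_range[2], length.out = grid_n)
  )
  res <- classify_vectors(grid, model)
  dv_cols <- paste0("dv_", model$classes)
  res$decision_value <- do.call(pmax, res[dv_cols])
  out <- dplyr::select(res, "amplitude", "phase_deg", "predicted",
                       "decision_value")
  class(out) <- c("ssvep_decision_surface", class(out))
  out
}
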