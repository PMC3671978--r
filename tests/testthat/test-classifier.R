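test_that("Z-test cleaning removes planted outliers and spares clean classes", {
  # a class of identical vectors is fully retained (zero spread, tests skip)
  same <- tibble::tibble(amplitude = rep(1, 50), phase_deg = rep(90, 50),
                         label = "1")
  w <- testthat::capture_warnings(kept <- z_test_clean(same))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2) # amplitude and phase spread are both zero
  expect_equal(nrow(kept), 50)

  # planted 10-SD amplitude outlier is excluded
  withr::with_seed(1, {
    d <- tibble::tibble(amplitude = rnorm(1000, 1, 0.1),
                        phase_deg = (rnorm(1000, 90, 5)) %% 360,
                        label = "1")
  })
  outlier_amp <- 1 + 10 * 0.1
  d$amplitude[500] <- outlier_amp
  kept <- z_test_clean(d)
  log <- attr(kept, "exclusion_log")
  expect_false(outlier_amp %in% kept$amplitude)
  expect_true(any(log$reason %in% c("amplitude", "both")))

  # rest vectors are never cleaned, even blatant outliers
  rest <- tibble::tibble(amplitude = c(rep(0.1, 30), 50),
                         phase_deg = withr::with_seed(2, runif(31, 0, 360)),
                         label = "rest")
  expect_equal(nrow(z_test_clean(rest)), 31)
})

test_that("Z-test exclusion fraction is near the nominal level for Gaussian features", {
  frac <- purrr::map_dbl(1:10, function(s) {
    withr::with_seed(s, {
      d <- tibble::tibble(amplitude = rnorm(1000, 1, 0.1),
                          phase_deg = (rnorm(1000, 180, 10)) %% 360,
                          label = "1")
    })
    log <- attr(z_test_clean(d, alpha = 0.05), "exclusion_log")
    # per-feature rejection rate; "both" counts for each feature
    sum(log$reason %in% c("amplitude", "both")) / 1000
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("one-against-all training yields one machine per class and separates clean clusters", {
  vecs <- separable_vectors()
  model <- svm_train(vecs, tune = FALSE)
  expect_s3_class(model, "ssvep_svm")
  expect_length(model$machines, 5)
  expect_equal(model$classes, c("1", "2", "3", "4", "rest"))
  res <- classify_vectors(vecs, model)
  expect_equal(mean(res$predicted == res$label), 1)
  expect_error(svm_train(dplyr::filter(vecs, label == "1")), ">= 2 classes")

  t <- tidy(model)
  expect_equal(t$class, model$classes)
  g <- glance(model)
  expect_equal(g$n_classes, 5L)
})

test_that("classification is the argmax of the decision values and is deterministic", {
  vecs <- separable_vectors(50)
  model <- svm_train(vecs, tune = FALSE)
  withr::with_seed(9, {
    probe <- tibble::tibble(amplitude = runif(1000, 0, 1.5),
                            phase_deg = runif(1000, 0, 360))
  })
  res <- classify_vectors(probe, model)
  dv <- as.matrix(res[paste0("dv_", model$classes)])
  expect_equal(res$predicted, model$classes[apply(dv, 1, which.max)])

  model2 <- svm_train(vecs, tune = FALSE)
  res2 <- classify_vectors(probe, model2)
  expect_identical(res$predicted, res2$predicted)
  expect_equal(predict(model, probe), res$predicted)
})

test_that("retraining with identical data, hyperparameters and seed reproduces predictions", {
  vecs <- separable_vectors(80, phase_sd = 15)
  withr::with_seed(10, {
    probe <- tibble::tibble(amplitude = runif(500, 0, 1.5),
                            phase_deg = runif(500, 0, 360))
  })
  m1 <- svm_train(vecs, tune = TRUE, tune_folds = 3, seed = 4)
  m2 <- svm_train(vecs, tune = TRUE, tune_folds = 3, seed = 4)
  expect_equal(m1$cost, m2$cost)
  expect_equal(m1$gamma, m2$gamma)
  expect_identical(classify_vectors(probe, m1)$predicted,
                   classify_vectors(probe, m2)$predicted)
})

test_that("predictions are invariant under a common phase rotation away from the seam", {
  vecs <- separable_vectors(80, phases = c(45, 135, 225, 315))
  rot <- 20
  rotated <- dplyr::mutate(vecs, phase_deg = (phase_deg + rot) %% 360)
  m0 <- svm_train(vecs, tune = FALSE)
  m1 <- svm_train(rotated, tune = FALSE)
  withr::with_seed(11, {
    probe <- tibble::tibble(amplitude = runif(400, 0.6, 1.4),
                            phase_deg = runif(400, 30, 330))
  })
  p0 <- classify_vectors(probe, m0)$predicted
  p1 <- classify_vectors(dplyr::mutate(probe, phase_deg = (phase_deg + rot) %% 360),
                         m1)$predicted
  expect_gte(mean(p0 == p1), 0.99)
})

test_that("the decision surface equals pointwise classification and bands the phase axis", {
  vecs <- separable_vectors(60)
  model <- svm_train(vecs, tune = FALSE)
  surf <- decision_surface(model, c(0, 1.5), c(0, 360), grid_n = 41)
  expect_equal(nrow(surf), 41^2)
  # grid nodes equal pointwise classify calls
  sub <- surf[sample.int(nrow(surf), 50), ]
  expect_equal(classify_vectors(sub[1:2], model)$predicted, sub$predicted)
  # at SSVEP-level amplitude the phase axis splits into 4 contiguous gaze bands
  row <- dplyr::filter(surf, abs(amplitude - 1.0125) < 1e-9)
  runs <- rle(row$predicted[order(row$phase_deg)])
  gaze_runs <- runs$values[runs$values != "rest"]
  expect_setequal(unique(gaze_runs), c("1", "2", "3", "4"))
  expect_lte(length(gaze_runs), 5) # 4 bands, at most one wrap-around split
  # degenerate grid
  expect_equal(nrow(decision_surface(model, c(0, 1), c(0, 360), grid_n = 2)), 4)
  expect_error(decision_surface(model, c(1, 0), c(0, 360)), "increasing")
  p <- ggplot2::autoplot(surf)
  expect_s3_class(p, "ggplot")
})
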