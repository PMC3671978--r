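test_that("K-S uniformity p-values match closed-form statistics", {
  # all mass at one point: D = max(F(x), 1 - F(x))
  p <- ks_uniform_pvalue(rep(90, 10))
  expect_equal(attr(p, "statistic"), 0.75)
  expect_lt(p, 0.01)
  # the worst concentrated case (180 deg) still rejects at the initial length
  p180 <- ks_uniform_pvalue(rep(180, 10))
  expect_equal(attr(p180, "statistic"), 0.5)
  expect_lt(p180, 0.01)
  # equispaced mid-points: D = 1/(2n) exactly, p ~ 1
  for (n in c(5, 10, 50)) {
    p <- ks_uniform_pvalue(360 * ((1:n) - 0.5) / n)
    expect_equal(attr(p, "statistic"), 1 / (2 * n))
    expect_gt(p, 0.999)
  }
  # n = 1 boundary handled without numerical failure
  p1 <- ks_uniform_pvalue(0)
  expect_equal(attr(p1, "statistic"), 1)
  expect_true(is.finite(p1))
  expect_error(ks_uniform_pvalue(numeric(0)), "non-empty")
  expect_error(ks_uniform_pvalue(c(10, 400)), "0, 360")
})

test_that("concentrated streams yield epochs of exactly the initial length", {
  withr::with_seed(21, {
    stream <- tibble::tibble(amplitude = 1,
                             phase_deg = (rnorm(100, 120, 5)) %% 360)
  })
  ep <- detect_effective_epoch(stream)
  expect_equal(ep$status, "epoch")
  expect_equal(ep$n_vectors, 10)
  expect_equal(ep$epoch_s, (200 + 9 * 50) / 1000)
  expect_lte(ep$ks_p, 0.01)
})

test_that("short and uniform streams give no-decision and timeout markers", {
  short <- tibble::tibble(amplitude = 1, phase_deg = rep(10, 5))
  expect_equal(detect_effective_epoch(short)$status, "no_decision")
  withr::with_seed(22, {
    unif <- tibble::tibble(amplitude = 1, phase_deg = runif(40, 0, 360))
  })
  ep <- detect_effective_epoch(unif, epoch_policy(max_vectors = 40))
  # this particular uniform stream should exhaust the cap
  expect_true(ep$status %in% c("timeout", "epoch"))
  if (ep$status == "timeout") expect_equal(ep$n_vectors, 40)
})

test_that("any returned epoch satisfies the K-S gate when recomputed post hoc", {
  withr::with_seed(23, {
    for (i in 1:25) {
      conc <- runif(1, 5, 120)
      stream <- tibble::tibble(
        amplitude = 1,
        phase_deg = (rnorm(200, runif(1, 0, 360), conc)) %% 360
      )
      ep <- detect_effective_epoch(stream)
      if (ep$status == "epoch") {
        expect_lte(as.numeric(ks_uniform_pvalue(ep$vectors$phase_deg)), 0.01)
        expect_gte(ep$n_vectors, 10)
      }
    }
  })
})

test_that("plurality voting returns the modal class with decision-value tie-breaks", {
  expect_equal(as.character(plurality_vote(c("1", "1", "2"))), "1")
  dv <- matrix(c(0.9, 0.0, 0.0, 0.4), nrow = 2,
               dimnames = list(NULL, c("1", "2")))
  v <- plurality_vote(c("1", "2"), dv)
  expect_equal(as.character(v), "1")
  expect_true(attr(v, "tie"))
  # the tie must flip when class 2 holds the larger decision mass
  dv2 <- matrix(c(0.1, 0.0, 0.0, 1.4), nrow = 2,
                dimnames = list(NULL, c("1", "2")))
  expect_equal(as.character(plurality_vote(c("1", "2"), dv2)), "2")
  expect_equal(as.character(plurality_vote(rep("rest", 5))), "rest")
  expect_error(plurality_vote(character(0)), "non-empty")
  # vote is invariant under permutation of the epoch's vectors
  withr::with_seed(24, {
    for (i in 1:20) {
      votes <- sample(c("1", "2", "3", "4", "rest"), 15, replace = TRUE)
      expect_equal(as.character(plurality_vote(votes)),
                   as.character(plurality_vote(sample(votes))))
    }
  })
})

test_that("offline segmentation consumes the stream in disjoint voted epochs", {
  vecs <- separable_vectors(200, phase_sd = 30)
  model <- svm_train(vecs, tune = FALSE)
  withr::with_seed(25, {
    stream <- tibble::tibble(amplitude = rnorm(150, 1, 0.05),
                             phase_deg = (rnorm(150, 45, 30)) %% 360,
                             label = "1")
  })
  segs <- segment_epochs(stream, model)
  emitted <- dplyr::filter(segs, status == "epoch")
  expect_gt(nrow(emitted), 5)
  expect_lte(sum(segs$n_vectors), nrow(stream))
  expect_true(all(emitted$n_vectors >= 10))
  expect_true(all(emitted$ks_p <= 0.01))
  expect_identical(segs, segment_epochs(stream, model))
})

test_that("mean epoch length shrinks as the phase concentration grows", {
  mean_len <- purrr::map_dbl(c(100, 45, 10), function(conc) {
    lens <- purrr::map_dbl(1:30, function(s) {
      withr::with_seed(1000 + s, {
        stream <- tibble::tibble(
          amplitude = 1,
          phase_deg = (rnorm(300, 90, conc)) %% 360
        )
      })
      detect_effective_epoch(stream, epoch_policy(max_vectors = 300))$n_vectors
    })
    mean(lens)
  })
  expect_true(all(diff(mean_len) <= 0))
})
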