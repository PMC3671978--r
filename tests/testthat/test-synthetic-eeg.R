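test_that("noiseless gaze recordings give a constant extracted phase", {
  params <- sim_params(noise_sd = 0, subject_phase_offset = 0, seed = 3)
  rec <- simulate_recording(1, 30, params)
  vecs <- vectors_from_recording(bandpass(rec))
  expect_equal(nrow(vecs), 597)
  # drop the filter start-up transient, then the phase is a single constant
  ph <- vecs$phase_deg[vecs$window_index >= 20]
  expect_lt(diff(range(((ph - ph[1] + 180) %% 360) - 180)), 0.01)
  # oracle: the same constant from a brute-force FFT of the filtered signal
  filt <- bandpass(rec)
  oracle <- Arg(fft_component_oracle(filt$amplitude[10001:10200])) * 180 / pi
  expect_phase_equal(ph[1], oracle %% 360, tol = 0.01)
})

test_that("noiseless phase differences recover the stimulus phase tags", {
  params <- sim_params(noise_sd = 0, subject_phase_offset = 137.3, seed = 3)
  phases <- purrr::map_dbl(1:4, function(cl) {
    vecs <- vectors_from_recording(bandpass(simulate_recording(cl, 5, params)))
    tail(vecs$phase_deg, 1)
  })
  cfg <- stimulus_config()
  for (a in 1:4) for (b in 1:4) {
    expect_phase_equal(phases[a] - phases[b],
                       cfg$phases[a] - cfg$phases[b], tol = 1)
  }
})

test_that("amplitude scales linearly and rest carries no locked component", {
  p1 <- sim_params(noise_sd = 0, subject_phase_offset = 10, ssvep_amplitude = 1)
  p2 <- sim_params(noise_sd = 0, subject_phase_offset = 10, ssvep_amplitude = 2)
  v1 <- vectors_from_recording(bandpass(simulate_recording(2, 5, p1)))
  v2 <- vectors_from_recording(bandpass(simulate_recording(2, 5, p2)))
  expect_equal(v2$amplitude, 2 * v1$amplitude, tolerance = 1e-12)
  # rest with zero noise is identically zero
  rest <- simulate_recording("rest", 2, p1)
  expect_true(all(rest$amplitude == 0))
  expect_error(simulate_recording("gaze", 2, p1), "rest")
})

test_that("rest-condition phases are compatible with uniformity", {
  # phases of 75%-overlapping windows are serially correlated (adjacent
  # windows share 150 of 200 samples), which inflates the one-sample K-S
  # rejection rate; the uniformity claim is about the phase distribution, so
  # test it on non-overlapping windows where K-S's independence assumption
  # holds, at close to the nominal 5% level
  reject <- purrr::map_lgl(1:100, function(s) {
    rec <- simulate_recording("rest", 30, sim_params(noise_sd = 1, seed = s))
    vecs <- vectors_from_recording(bandpass(rec))
    ph <- vecs$phase_deg[seq(1, nrow(vecs), by = 4)]
    ks_uniform_pvalue(ph) < 0.05
  })
  expect_lte(mean(reject), 0.10)
})

test_that("rest phases pass a chi-square uniformity check in the large-sample limit", {
  rec <- simulate_recording("rest", 510, sim_params(noise_sd = 1, seed = 11))
  vecs <- vectors_from_recording(bandpass(rec))
  expect_gte(nrow(vecs), 1e4)
  counts <- table(cut(vecs$phase_deg, breaks = seq(0, 360, by = 10)))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("recordings are bit-identical under identical params and seed", {
  p <- sim_params(noise_sd = 1.5, seed = 99)
  r1 <- simulate_recording(3, 4, p)
  r2 <- simulate_recording(3, 4, p)
  expect_identical(r1$amplitude, r2$amplitude)
  s1 <- simulate_online_session(p, n_trials_per_class = 2, gaze_s = 2)
  s2 <- simulate_online_session(p, n_trials_per_class = 2, gaze_s = 2)
  expect_identical(s1$recording$amplitude, s2$recording$amplitude)
  expect_identical(s1$trials, s2$trials)
})

test_that("online sessions cue every class equally often in randomized order", {
  sess <- simulate_online_session(sim_params(seed = 5), n_trials_per_class = 20,
                                  gaze_s = 2)
  expect_equal(nrow(sess$trials), 80)
  expect_true(all(table(sess$trials$cue_class) == 20))
  expect_false(all(sess$trials$cue_class == rep(c("1", "2", "3", "4"), 20)))
  # trial boundaries sit on the flicker-cycle grid
  expect_true(all(sess$trials$start_sample %% 50 == 0))
})

test_that("the transition span is excluded from per-trial vector streams", {
  sess <- simulate_online_session(sim_params(noise_sd = 0.5, seed = 2),
                                  n_trials_per_class = 2, gaze_s = 2)
  vecs <- vectors_from_session(sess, transition_exclude = 10)
  first <- dplyr::summarise(dplyr::group_by(vecs, trial),
                            first_start = min(start_sample))
  starts <- sess$trials$start_sample[match(first$trial, sess$trials$trial)]
  # first retained window begins at least 0.5 s after trial onset
  expect_true(all(first$first_start - starts >= 500))
})
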