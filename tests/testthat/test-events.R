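test_that("amplitude histogram fit locates telegraph levels", {
  sp <- channel_sim_spec(1, 0.4, 10.8, mean_open_time = 20, duration = 20000)
  tr <- gen_single_channel_trace(sp, noise_spec(trace_noise_sd = 1, seed = 21))
  fit <- amplitude_histogram_fit(tr, 2)
  expect_true(fit$convergence$converged)
  expect_equal(fit$means[1], 0, tolerance = 0.3)
  expect_equal(fit$means[2], 10.8, tolerance = 0.3)
  expect_equal(fit$unitary_amplitude, 10.8, tolerance = 0.3)
  expect_equal(sum(fit$weights), 1)
  expect_equal(fit$baseline, fit$means[1], tolerance = 0.3)

  # cross-check level means against an EM mixture oracle
  if (requireNamespace("mclust", quietly = TRUE)) {
    withr::local_package("mclust")
    em <- mclust::Mclust(tr$value_pA[seq(1, nrow(tr), by = 10)], G = 2,
                         modelNames = "V", verbose = FALSE)
    expect_equal(sort(fit$means), sort(as.numeric(em$parameters$mean)),
                 tolerance = 0.3)
  }

  # pure baseline: one apparent mode, flag raised
  base <- gen_single_channel_trace(channel_sim_spec(1, 0, 10.8,
                                                    duration = 5000),
                                   noise_spec(trace_noise_sd = 1, seed = 22))
  bfit <- amplitude_histogram_fit(base, 2)
  expect_false(bfit$convergence$converged)
})

test_that("half-amplitude idealization recovers the generator dwell path", {
  expect_error(idealize_trace(rep(0, 100), 0, 0, sample_interval = 1),
               "non-zero")

  # constant baseline gives one level-0 segment
  id0 <- idealize_trace(rep(0.01, 500), baseline = 0, unitary = 2,
                        sample_interval = 0.5)
  expect_equal(nrow(id0$segments), 1L)
  expect_equal(id0$segments$level, 0L)

  # near-noiseless alternation reproduces the generator's state sequence
  sp <- channel_sim_spec(1, 0.3, 5, mean_open_time = 15, duration = 20000)
  tr <- gen_single_channel_trace(sp, noise_spec(trace_noise_sd = 1e-9,
                                                seed = 23))
  # with dead-time censoring off the generator state path is recovered exactly
  id_full <- idealize_trace(tr, 0, 5, min_samples = 1)
  recon <- inverse.rle(list(lengths = round(id_full$segments$duration_ms / 0.1),
                            values = id_full$segments$level))
  expect_equal(recon, as.integer(attr(tr, "level")))
  # default two-sample dead time censors only sub-resolution flickers
  id <- idealize_trace(tr, 0, 5)
  npo_full <- estimate_npo(id_full)
  expect_equal(estimate_npo(id), npo_full, tolerance = 1e-3)

  # downward-deflecting openings: negative unitary behaves identically
  sp_dn <- channel_sim_spec(1, 0.3, -5, mean_open_time = 15, duration = 20000)
  tr_dn <- gen_single_channel_trace(sp_dn, noise_spec(trace_noise_sd = 1e-9,
                                                      seed = 23))
  id_dn <- idealize_trace(tr_dn, 0, -5)
  expect_equal(id_dn$segments$level, id$segments$level)

  # adding a constant offset changes nothing once baseline is re-estimated
  tr_off <- tr
  tr_off$value_pA <- tr_off$value_pA + 8
  id_off <- idealize_trace(tr_off, baseline = 8, unitary = 5)
  expect_equal(id_off$segments, id$segments)
})

test_that("NPo estimates match the stationary expectation", {
  seg <- data.frame(start_ms = c(0, 10), duration_ms = c(10, 10),
                    level = c(0L, 0L))
  closed <- structure(list(segments = seg, unitary_amplitude = 1,
                           baseline = 0, total_ms = 20),
                      class = "idealized_trace")
  expect_equal(estimate_npo(closed), 0)

  # single channel at the drug-stimulated open probability, 60 s
  sp <- channel_sim_spec(1, 0.211, 10.8, mean_open_time = 10,
                         duration = 60000)
  tr <- gen_single_channel_trace(sp, noise_spec(seed = 7))
  po <- estimate_npo(idealize_trace(tr, 0, 10.8))
  expect_lt(abs(po - 0.211) / 0.211, 0.15)

  # three channels, NPo converges to N x Po = 1.45
  sp3 <- channel_sim_spec(3, 1.45 / 3, 1.2, mean_open_time = 10,
                          duration = 60000)
  tr3 <- gen_single_channel_trace(sp3, noise_spec(seed = 11))
  npo <- estimate_npo(idealize_trace(tr3, 0, 1.2))
  expect_lt(abs(npo - 1.45) / 1.45, 0.15)
})

test_that("action-current detection is exact at high SNR", {
  withr::with_seed(31, {
    flat <- data.frame(time_ms = seq(0, 20000, by = 0.2),
                       value_pA = rnorm(100001, 0, 2))
  })
  expect_length(detect_action_currents(flat)$event_times_s, 0)
  expect_error(detect_action_currents(flat, k_sd = 0), "> 0")

  tr <- gen_action_current_train(1.21, 100, noise = noise_spec(seed = 3))
  truth <- attr(tr, "event_times_s")
  det <- detect_action_currents(tr)
  # match detected to true events within 10 ms
  hits <- vapply(truth, function(t0)
    any(abs(det$event_times_s - t0) < 0.010), logical(1))
  # events closer than the lockout merge; exclude those pairs from recall
  sep <- c(TRUE, diff(truth) > 0.020)
  recall <- mean(hits[sep])
  precision <- mean(vapply(det$event_times_s, function(t0)
    any(abs(truth - t0) < 0.010), logical(1)))
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.99)
  expect_equal(firing_frequency(det), 1.21, tolerance = 3 * sqrt(121) / 121)
})

test_that("firing frequency is events over duration", {
  expect_equal(firing_frequency(event_train(numeric(0), 10)), 0)
  expect_equal(firing_frequency(
    event_train(seq(0.1, 99.9, length.out = 121), 100)), 1.21)
  expect_equal(firing_frequency(
    event_train(seq(0.5, 99.5, length.out = 54), 100)), 0.54)
  expect_error(event_train(c(1, 2), 0), "> 0")
  expect_error(event_train(c(2, 1), 10), "increasing")
})
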