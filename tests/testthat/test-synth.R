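test_that("whole-cell sweep generator reproduces Boltzmann steady states", {
  proto <- step_protocol(step_duration = 2000, sample_interval = 1)
  quiet <- noise_spec(trace_noise_sd = 0, cell_cv = 0, seed = 1)

  # noiseless step to V_half ends at half-maximal conductance
  sw <- gen_ikm_sweeps(proto, g_max = 1, v_half = -26.8, q = 1.86,
                       noise = quiet)
  ep <- end_of_pulse(sw)
  g_end <- ep$i_pA / (ep$step_mV - (-91))
  expect_equal(g_end, eval_boltzmann(ep$step_mV, -26.8, 1.86),
               tolerance = 1e-3)

  # hyperpolarizing activation shift raises current at -10 mV
  ctrl <- end_of_pulse(gen_ikm_sweeps(proto, 1, -26.8, 1.86, noise = quiet))
  ngen <- end_of_pulse(gen_ikm_sweeps(proto, 1, -44.3, 2.01, noise = quiet))
  expect_gt(ngen$i_pA[ngen$step_mV == -10], ctrl$i_pA[ctrl$step_mV == -10])

  # instantaneous relaxation limit: trace is a step at the steady value
  fast <- gen_ikm_sweeps(proto, 1, -26.8, 1.86, tau_relax = 0, noise = quiet)
  one <- fast[fast$cell_id == 1 & fast$step_mV == -10, ]
  i_ss <- eval_boltzmann(-10, -26.8, 1.86) * (-10 + 91)
  expect_equal(unique(round(one$value_pA, 10)), round(i_ss, 10))
})

test_that("dose-response generator normalizes and orders responses", {
  conc <- c(0.1, 1, 3, 10, 30, 100, 300)
  quiet <- noise_spec(0, 0, seed = 2)
  tab <- gen_dose_response(conc, e_max = 100, ec50 = 9.8, noise = quiet,
                           n_cells = 5)
  expect_equal(mean(tab$response_pct[tab$conc_uM == 300]), 100)
  mu <- tapply(tab$response_pct, tab$conc_uM, mean)
  expect_true(all(diff(mu[order(as.numeric(names(mu)))]) >= 0))

  # with a saturating top concentration the half point sits near 50%
  tab2 <- gen_dose_response(c(9.8, 1e5), ec50 = 9.8, noise = quiet)
  expect_equal(tab2$response_pct[tab2$conc_uM == 9.8], 50, tolerance = 1e-3)

  expect_error(gen_dose_response(numeric(0)), "non-empty")
})

test_that("telegraph-channel generator matches its stationary law", {
  # closed channel: baseline plus noise only
  sp0 <- channel_sim_spec(1, 0, 2, duration = 1000)
  tr0 <- gen_single_channel_trace(sp0, noise_spec(seed = 5))
  expect_true(all(attr(tr0, "level") == 0))
  expect_lt(max(abs(tr0$value_pA)), 2)

  # occupancy converges to n * p on a long trace
  sp <- channel_sim_spec(1, 0.211, 10.8, mean_open_time = 10,
                         duration = 60000)
  tr <- gen_single_channel_trace(sp, noise_spec(seed = 7))
  frac <- mean(attr(tr, "level"))
  n_cyc <- 60000 / (10 + 10 * (1 - 0.211) / 0.211)
  se <- sqrt(0.211 * 0.789 / n_cyc)
  expect_lt(abs(frac - 0.211), 3 * se)

  # three channels at p = 0.5: occupancy histogram is Binomial(3, 0.5)
  sp3 <- channel_sim_spec(3, 0.5, 1, mean_open_time = 10, duration = 60000)
  tr3 <- gen_single_channel_trace(sp3, noise_spec(seed = 8))
  obs <- tabulate(attr(tr3, "level") + 1L, 4L)
  expfreq <- dbinom(0:3, 3, 0.5) * sum(obs)
  chi2 <- sum((obs - expfreq)^2 / expfreq)
  # dwell-correlated samples inflate chi2; compare against an effective-n
  # version using independent cycles
  n_eff <- 60000 / 20
  chi2_eff <- chi2 * n_eff / sum(obs)
  expect_lt(chi2_eff, qchisq(0.999, df = 3))

  expect_error(gen_single_channel_trace(
    channel_sim_spec(1, 0.5, 1, mean_open_time = 0.2), sample_interval = 0.1),
    "unresolvable")
})

test_that("action-current train is a homogeneous Poisson process", {
  tr0 <- gen_action_current_train(0, 20, noise = noise_spec(seed = 1))
  expect_length(attr(tr0, "event_times_s"), 0)

  tr <- gen_action_current_train(1.21, 100, noise = noise_spec(seed = 3))
  n_ev <- length(attr(tr, "event_times_s"))
  expect_lt(abs(n_ev - 121), 3 * sqrt(121))

  trks <- gen_action_current_train(10, 10, noise = noise_spec(seed = 4))
  iei <- diff(attr(trks, "event_times_s"))
  expect_gt(ks.test(iei, "pexp", rate = 10)$p.value, 0.01)

  expect_error(gen_action_current_train(-1, 10), ">= 0")
})

test_that("unitary i-V generator is ohmic", {
  quiet <- noise_spec(seed = 6)
  iv <- gen_single_channel_iv(180, reversal = 0, potentials = c(-60, 0, 60),
                              noise = quiet)
  expect_equal(iv$i_pA[iv$v_mV == 0], 0)
  expect_equal(iv$i_pA[iv$v_mV == 60], 10.8)
  # 178 vs 180 pS differ by < 0.15 pA at every potential in +-60 mV
  a <- gen_single_channel_iv(178, noise = quiet)
  b <- gen_single_channel_iv(180, noise = quiet)
  expect_lt(max(abs(a$i_pA - b$i_pA)), 0.15)
  expect_error(gen_single_channel_iv(180, potentials = 10), ">= 2")
})

test_that("identical seeds give identical synthetic data", {
  conc <- c(1, 3, 10, 30, 100)
  a <- gen_dose_response(conc, noise = noise_spec(5, 0.1, seed = 42),
                         n_cells = 4)
  b <- gen_dose_response(conc, noise = noise_spec(5, 0.1, seed = 42),
                         n_cells = 4)
  d <- gen_dose_response(conc, noise = noise_spec(5, 0.1, seed = 43),
                         n_cells = 4)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$response_pct, d$response_pct)))

  t1 <- gen_single_channel_trace(channel_sim_spec(1, 0.3, 2, duration = 2000),
                                 noise_spec(seed = 9))
  t2 <- gen_single_channel_trace(channel_sim_spec(1, 0.3, 2, duration = 2000),
                                 noise_spec(seed = 9))
  expect_identical(t1, t2)

  # generator streams leave the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_dose_response(conc, noise = noise_spec(seed = 1)))
  expect_identical(before, .Random.seed)
})
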