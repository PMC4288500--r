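test_that("Hill evaluation has midpoint symmetry and standard form", {
  for (nh in c(0.5, 1, 2, 3.7))
    expect_equal(eval_hill(9.8, 100, 9.8, nh), 50)
  expect_equal(eval_hill(30, 100, 10, 2), 90)
  # the printed un-exponentiated denominator only agrees at n_h = 1
  expect_equal(eval_hill(30, 100, 10, 1, paper_form = TRUE),
               eval_hill(30, 100, 10, 1))
  expect_false(eval_hill(30, 100, 10, 2, paper_form = TRUE) ==
                 eval_hill(30, 100, 10, 2))
  expect_error(eval_hill(-1, 100, 10), ">= 0")
})

test_that("Hill fit recovers parameters and flags degenerate input", {
  conc <- c(0.1, 1, 3, 10, 30, 100, 300)
  tab <- data.frame(conc_uM = conc, response_pct = eval_hill(conc, 100, 9.8))
  fit <- fit_hill(tab)
  expect_true(fit$convergence$converged)
  expect_equal(unname(fit$estimate["ec50"]), 9.8, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["n_h"]), 1, tolerance = 1e-6)

  flat <- data.frame(conc_uM = conc, response_pct = rep(50, 7))
  ffit <- fit_hill(flat)
  expect_false(ffit$convergence$converged)
  expect_match(ffit$convergence$message, "degenerate")
})

test_that("Hill fit agrees with the coarse-to-fine grid-search oracle", {
  conc <- rep(c(0.3, 1, 3, 10, 30, 100, 300), each = 8)
  withr::with_seed(11, {
    y <- eval_hill(conc, 100, 9.8, 1.3) + rnorm(length(conc), 0, 4)
  })
  fit <- fit_hill(data.frame(conc_uM = conc, response_pct = y))
  oracle <- hill_grid_oracle(conc, y, c(2, 40), c(0.4, 3))
  expect_equal(unname(fit$estimate["ec50"]), unname(oracle[["ec50"]]),
               tolerance = 0.02)
  expect_equal(unname(fit$estimate["n_h"]), unname(oracle[["n_h"]]),
               tolerance = 0.02)
})

test_that("Boltzmann evaluation matches direct computation and ordering", {
  expect_equal(eval_boltzmann(-26.8, -26.8, 1.86), 0.5)
  # control activation at -10 mV, RT/F = 25.42 mV at 295 K
  expect_equal(eval_boltzmann(-10, -26.8, 1.86, 295), 0.7736, tolerance = 1e-3)
  v <- seq(-50, 10, by = 1)
  g_ctrl <- eval_boltzmann(v, -26.8, 1.86)
  g_ngen <- eval_boltzmann(v, -44.3, 2.01)
  expect_true(all(diff(g_ctrl) > 0))       # strictly increasing in V
  expect_true(all(g_ngen > g_ctrl))        # leftward-shifted curve is larger
})

test_that("Boltzmann fit round-trips control and drug-shifted parameters", {
  v <- seq(-50, 10, by = 10)
  for (par in list(c(-26.8, 1.86), c(-44.3, 2.01))) {
    g <- eval_boltzmann(v, par[1], par[2])
    fit <- fit_boltzmann(data.frame(v_mV = v, g = g))
    expect_true(fit$convergence$converged)
    expect_equal(unname(fit$estimate["v_half"]), par[1], tolerance = 1e-6)
    expect_equal(unname(fit$estimate["q"]), par[2], tolerance = 1e-6)
  }
  flat <- data.frame(v_mV = v, g = rep(0.7, length(v)))
  expect_false(fit_boltzmann(flat)$convergence$converged)

  # noisy fit agrees with the grid-search oracle
  withr::with_seed(12, {
    g <- eval_boltzmann(v, -26.8, 1.86) + rnorm(length(v), 0, 0.02)
  })
  fit <- fit_boltzmann(data.frame(v_mV = v, g = g))
  oracle <- boltzmann_grid_oracle(v, g, c(-60, 0), c(0.5, 4))
  expect_equal(unname(fit$estimate["v_half"]), unname(oracle[["v_half"]]),
               tolerance = 0.05)
  expect_equal(unname(fit$estimate["q"]), unname(oracle[["q"]]),
               tolerance = 0.02)
})

test_that("whole-cell conductance slope is windowed ordinary least squares", {
  v <- seq(-50, 10, by = 10)
  iv <- data.frame(v_mV = v, i_pA = 2.11 * v + 150)
  fit <- conductance_slope(iv, c(-30, -10))
  expect_equal(fit$slope_nS, 2.11, tolerance = 1e-12)
  expect_equal(fit$n, 3L)

  two <- conductance_slope(data.frame(v_mV = c(-30, -10), i_pA = c(0, 29)),
                           c(-30, -10))
  expect_equal(two$slope_nS, 29 / 20)

  # noisy seeded points against hand-computed normal equations
  withr::with_seed(13, {
    y <- 1.45 * v + 80 + rnorm(length(v), 0, 3)
  })
  fit2 <- conductance_slope(data.frame(v_mV = v, i_pA = y), c(-50, 10))
  sxx <- sum((v - mean(v))^2)
  beta <- sum((v - mean(v)) * (y - mean(y))) / sxx
  expect_equal(fit2$slope_nS, beta, tolerance = 1e-12)

  expect_error(conductance_slope(iv, c(5, 9)), ">= 2 points")
})

test_that("single-channel conductance regression reports pS", {
  v <- seq(-60, 60, by = 20)
  for (g in c(178, 180)) {
    amp <- data.frame(v_mV = v, i_pA = g / 1000 * v)
    expect_equal(single_channel_conductance(amp)$conductance_pS, g,
                 tolerance = 1e-9)
    expect_equal(single_channel_conductance(amp, reversal = 0)$conductance_pS,
                 g, tolerance = 1e-9)
  }
  dup <- data.frame(v_mV = c(60, 60), i_pA = c(10.8, 10.8))
  expect_error(single_channel_conductance(dup), "2 distinct")
})
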