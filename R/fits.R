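#' Hill concentration-response value
#'
#' Standard Hill function `E_max * C^nH / (EC50^nH + C^nH)`.  The variant
#' with an un-exponentiated denominator term (`EC50 + C^nH`), sometimes seen
#' in print, is dimensionally inconsistent for `nH != 1`; it is available
#' behind `paper_form = TRUE` for comparison.
#'
#' @param conc concentration (uM); must be >= 0.
#' @param e_max maximal response (percent of maximal increase).
#' @param ec50 half-maximal concentration (uM), > 0.
#' @param n_h Hill coefficient, > 0.
#' @param paper_form use the un-exponentiated denominator variant.
#' @return response on the scale of `e_max`.
#' @examples
#' eval_hill(9.8, e_max = 100, ec50 = 9.8)  # 50
#' @export
eval_hill <- function(conc, e_max, ec50, n_h = 1, paper_form = FALSE) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (ec50 <= 0 || e_max <= 0 || n_h <= 0)
    stop("e_max, ec50 and n_h must be > 0")
  cn <- conc^n_h
  if (paper_form) e_max * cn / (ec50 + cn) else e_max * cn / (ec50^n_h + cn)
}

#' Boltzmann voltage-activation value
#'
#' Relative conductance `1 / (1 + exp(-(V - V_half) * q * F / (R * T)))` with
#' `q` the apparent gating charge in elementary charges and V in mV.
#'
#' @param v membrane potential (mV).
#' @param v_half half-activation voltage (mV).
#' @param q apparent gating charge (elementary charges), > 0.
#' @param temperature_K absolute temperature; default 295 K (room
#'   temperature recordings).
#' @return relative conductance in (0, 1), strictly increasing in `v`.
#' @examples
#' eval_boltzmann(-26.8, v_half = -26.8, q = 1.86)  # 0.5
#' @export
eval_boltzmann <- function(v, v_half, q, temperature_K = DEFAULT_TEMP_K) {
  if (q <= 0) stop("gating charge q must be > 0")
  if (temperature_K <= 0) stop("temperature must be > 0")
  vt <- thermal_voltage_mV(temperature_K)
  1 / (1 + exp(-(v - v_half) * q / vt))
}

fit_flag <- function(converged, message = NULL) {
  list(converged = converged, message = message)
}

#' Fit the Hill equation to a concentration-response table
#'
#' Nonlinear least squares on pooled per-cell responses.  Initialization:
#' `e_max` at the maximum mean response, `ec50` at the concentration whose
#' mean response is nearest half-maximal, `n_h` at 1.
#'
#' @param table data.frame with columns `conc_uM` and `response_pct`
#'   (a `cell_id` column is allowed and ignored by the pooled fit).
#' @param init optional named list overriding starting values
#'   (`e_max`, `ec50`, `n_h`).
#' @return object of class `hill_fit`: list with `estimate` (named vector
#'   e_max, ec50, n_h), `se`, and `convergence` (list with `converged`,
#'   `message`).  Non-convergence is flagged, never silent.
#' @export
fit_hill <- function(table, init = NULL) {
  stopifnot(all(c("conc_uM", "response_pct") %in% names(table)))
  conc <- table$conc_uM
  y <- table$response_pct
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct concentrations spanning the midpoint")
  mu <- tapply(y, conc, mean)
  cu <- as.numeric(names(mu))
  if (diff(range(mu)) < 1e-8 * max(abs(mu), 1))
    return(structure(list(estimate = NULL, se = NULL,
                          convergence = fit_flag(FALSE, "degenerate input: responses show no concentration dependence")),
                     class = "hill_fit"))
  start <- list(e_max = max(mu), ec50 = cu[which.min(abs(mu - max(mu) / 2))],
                n_h = 1)
  if (!is.null(init)) start[names(init)] <- init
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ e_max * conc^n_h / (ec50^n_h + conc^n_h),
                      start = start,
                      lower = c(e_max = 1e-8, ec50 = 1e-8, n_h = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(estimate = NULL, se = NULL,
                          convergence = fit_flag(FALSE, conditionMessage(fit))),
                     class = "hill_fit"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(estimate = est, se = setNames(se, names(est)),
                 convergence = fit_flag(TRUE)),
            class = "hill_fit")
}

#' Fit the Boltzmann activation curve to conductance-voltage points
#'
#' Least-squares fit of `G = G_max / (1 + exp(-(V - V_half) q F / RT))`.
#' Initialization: `v_half` at the voltage of half-range conductance,
#' `q` at 2, `g_max` at the maximum observed conductance.
#'
#' @param gv data.frame with columns `v_mV` and `g` (conductance, any
#'   consistent unit; relative conductance works too).
#' @param temperature_K absolute temperature (K).
#' @param init optional named list of starting values (`g_max`, `v_half`, `q`).
#' @return object of class `boltzmann_fit`: `estimate` (g_max, v_half, q),
#'   `se`, `temperature_K`, `convergence`.
#' @export
fit_boltzmann <- function(gv, temperature_K = DEFAULT_TEMP_K, init = NULL) {
  stopifnot(all(c("v_mV", "g") %in% names(gv)))
  if (length(unique(gv$v_mV)) < 4)
    stop("need >= 4 voltages spanning the inflection")
  v <- gv$v_mV
  g <- gv$g
  if (diff(range(g)) <= 0)
    return(structure(list(estimate = NULL, se = NULL,
                          temperature_K = temperature_K,
                          convergence = fit_flag(FALSE, "degenerate input: conductances show no spread")),
                     class = "boltzmann_fit"))
  vt <- thermal_voltage_mV(temperature_K)
  half <- min(g) + diff(range(g)) / 2
  start <- list(g_max = max(g), v_half = v[which.min(abs(g - half))], q = 2)
  if (!is.null(init)) start[names(init)] <- init
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ g_max / (1 + exp(-(v - v_half) * q / vt)),
                      start = start,
                      lower = c(g_max = 1e-10, v_half = -200, q = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(estimate = NULL, se = NULL,
                          temperature_K = temperature_K,
                          convergence = fit_flag(FALSE, conditionMessage(fit))),
                     class = "boltzmann_fit"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(estimate = est, se = setNames(se, names(est)),
                 temperature_K = temperature_K, convergence = fit_flag(TRUE)),
            class = "boltzmann_fit")
}

#' Whole-cell conductance as the I-V slope in a voltage window
#'
#' Ordinary least squares of current (pA) on voltage (mV) restricted to the
#' closed window; the slope pA/mV is the chord conductance in nS.
#'
#' @param iv data.frame with columns `v_mV` and `i_pA`.
#' @param window length-2 numeric, `c(lower, upper)` in mV.
#' @return list of class `conductance_fit`: `slope_nS`, `intercept_pA`,
#'   `se_slope`, `window`, `n`.
#' @examples
#' iv <- data.frame(v_mV = c(-30, -20, -10), i_pA = 2.11 * c(-30, -20, -10) + 80)
#' conductance_slope(iv, c(-30, -10))$slope_nS  # 2.11
#' @export
conductance_slope <- function(iv, window = c(-30, -10)) {
  stopifnot(all(c("v_mV", "i_pA") %in% names(iv)))
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(lower, upper) with lower < upper")
  sel <- iv$v_mV >= window[1] & iv$v_mV <= window[2]
  if (sum(sel) < 2) stop("need >= 2 points inside the voltage window")
  fit <- lm(i_pA ~ v_mV, data = iv[sel, ])
  cf <- coef(fit)
  ses <- tryCatch(suppressWarnings(sqrt(diag(vcov(fit)))),
                  error = function(e) c(NA, NA))
  structure(list(slope_nS = unname(cf[2]), intercept_pA = unname(cf[1]),
                 se_slope = unname(ses[2]), window = window, n = sum(sel)),
            class = "conductance_fit")
}

#' Single-channel conductance by linear regression of unitary amplitudes
#'
#' Regression of mean unitary current amplitude (pA) on holding potential
#' (mV); the slope is converted to pS.  With `reversal` given, the line is
#' constrained through the reversal potential; otherwise both slope and
#' reversal are fitted.
#'
#' @param amp data.frame with columns `v_mV` and `i_pA`.
#' @param reversal reversal potential in mV, or `NULL` to fit it.
#' @return list of class `scc_fit`: `conductance_pS`, `reversal_mV`, `se_pS`.
#' @examples
#' a <- data.frame(v_mV = seq(-60, 60, 20), i_pA = 0.180 * seq(-60, 60, 20))
#' single_channel_conductance(a)$conductance_pS  # 180
#' @export
single_channel_conductance <- function(amp, reversal = NULL) {
  stopifnot(all(c("v_mV", "i_pA") %in% names(amp)))
  if (length(unique(amp$v_mV)) < 2)
    stop("need amplitudes at >= 2 distinct potentials")
  if (is.null(reversal)) {
    fit <- lm(i_pA ~ v_mV, data = amp)
    slope <- coef(fit)[["v_mV"]]
    rev <- -coef(fit)[["(Intercept)"]] / slope
    se <- suppressWarnings(sqrt(diag(vcov(fit)))[["v_mV"]])
  } else {
    x <- amp$v_mV - reversal
    fit <- lm(amp$i_pA ~ x - 1)
    slope <- coef(fit)[["x"]]
    rev <- reversal
    se <- suppressWarnings(sqrt(diag(vcov(fit)))[["x"]])
  }
  structure(list(conductance_pS = 1000 * slope, reversal_mV = rev,
                 se_pS = 1000 * se),
            class = "scc_fit")
}
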