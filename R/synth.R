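#' Noise and variability specification for the synthetic generators
#'
#' @param trace_noise_sd additive Gaussian noise SD on traces, in the trace's
#'   current units (pA).
#' @param cell_cv coefficient of variation for per-cell parameter jitter
#'   (lognormal on amplitude-like parameters, Gaussian on location-like
#'   parameters scaled by their magnitude).
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(trace_noise_sd = 0, cell_cv = 0, seed = 1L) {
  if (trace_noise_sd < 0 || cell_cv < 0)
    stop("trace_noise_sd and cell_cv must be >= 0")
  structure(list(trace_noise_sd = trace_noise_sd, cell_cv = cell_cv,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Voltage-step protocol
#'
#' @param holding_potential holding level, mV.
#' @param step_levels vector of step potentials, mV (non-empty).
#' @param step_duration step length, ms (> 0).
#' @param sample_interval sampling interval, ms (> 0).
#' @return list of class `step_protocol`.
#' @export
step_protocol <- function(holding_potential = -20,
                          step_levels = seq(-50, 10, by = 10),
                          step_duration = 2000, sample_interval = 1) {
  if (!length(step_levels)) stop("step_levels must be non-empty")
  if (step_duration <= 0 || sample_interval <= 0)
    stop("durations and intervals must be > 0")
  structure(list(holding_potential = holding_potential,
                 step_levels = step_levels, step_duration = step_duration,
                 sample_interval = sample_interval),
            class = "step_protocol")
}

#' Stochastic single-channel simulation specification
#'
#' @param n_channels number of independent channels in the patch.
#' @param open_probability per-channel stationary open probability in `[0,1]`.
#' @param unitary_amplitude single-channel current, pA (non-zero; negative for
#'   downward-deflecting cell-attached openings).
#' @param mean_open_time mean open dwell, ms.
#' @param mean_closed_time mean closed dwell, ms; if `NULL`, derived from
#'   `open_probability` as `mean_open_time * (1 - p) / p`.
#' @param duration trace length, ms.
#' @return list of class `channel_sim_spec`.
#' @export
channel_sim_spec <- function(n_channels = 1, open_probability = 0.5,
                             unitary_amplitude = 1, mean_open_time = 10,
                             mean_closed_time = NULL, duration = 60000) {
  if (open_probability < 0 || open_probability > 1)
    stop("open_probability must be in [0, 1]")
  if (unitary_amplitude == 0) stop("unitary_amplitude must be non-zero")
  if (is.null(mean_closed_time)) {
    mean_closed_time <- if (open_probability %in% c(0, 1)) Inf
    else mean_open_time * (1 - open_probability) / open_probability
  }
  if (mean_open_time <= 0 || mean_closed_time <= 0)
    stop("dwell means must be > 0")
  p_implied <- mean_open_time / (mean_open_time + mean_closed_time)
  if (is.finite(mean_closed_time) &&
      abs(p_implied - open_probability) > 1e-6)
    stop("dwell means inconsistent with open_probability")
  structure(list(n_channels = as.integer(n_channels),
                 open_probability = open_probability,
                 unitary_amplitude = unitary_amplitude,
                 mean_open_time = mean_open_time,
                 mean_closed_time = mean_closed_time, duration = duration),
            class = "channel_sim_spec")
}

# Named RNG stream per generator: all randomness flows from one integer seed
# plus a fixed per-generator offset; the caller's RNG state is untouched.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max, kind = "Mersenne-Twister")
  expr
}

STREAM <- c(ikm = 101L, dose = 202L, channel = 303L, train = 404L, iv = 505L)

#' Generate whole-cell M-current step sweeps
#'
#' Each sweep relaxes mono-exponentially from the holding-level current to
#' the Boltzmann steady state `G_max * boltz(V_step) * (V_step - reversal)`
#' with time constant `tau_relax`, plus additive Gaussian noise.  Per-cell
#' `G_max` is jittered lognormally and `V_half` normally by `cell_cv`.
#'
#' @param protocol [step_protocol()].
#' @param g_max maximal conductance, nS.
#' @param v_half,q Boltzmann activation parameters (mV, elementary charges).
#' @param tau_relax relaxation time constant, ms (Kv7-like kinetics; does not
#'   affect end-of-pulse steady values).
#' @param reversal K+ reversal potential, mV.
#' @param noise [noise_spec()].
#' @param n_cells number of simulated cells.
#' @param temperature_K recording temperature.
#' @return data.frame (class `sweep_set`) with columns `cell_id`, `sweep_id`,
#'   `step_mV`, `time_ms`, `value_pA`; the protocol is kept as an attribute.
#' @export
gen_ikm_sweeps <- function(protocol, g_max, v_half, q, tau_relax = 150,
                           reversal = -91, noise = noise_spec(),
                           n_cells = 1, temperature_K = DEFAULT_TEMP_K) {
  stopifnot(inherits(protocol, "step_protocol"), inherits(noise, "noise_spec"))
  if (!all(is.finite(c(g_max, v_half, q, tau_relax, reversal))))
    stop("generator parameters must be finite")
  with_stream(noise$seed, STREAM[["ikm"]], {
    tt <- seq(0, protocol$step_duration, by = protocol$sample_interval)
    out <- vector("list", n_cells * length(protocol$step_levels))
    k <- 0L
    for (cell in seq_len(n_cells)) {
      gm_c <- g_max * rlnorm(1, -noise$cell_cv^2 / 2, noise$cell_cv)
      vh_c <- v_half + rnorm(1, 0, noise$cell_cv * abs(v_half))
      i_hold <- gm_c *
        eval_boltzmann(protocol$holding_potential, vh_c, q, temperature_K) *
        (protocol$holding_potential - reversal)
      for (sw in seq_along(protocol$step_levels)) {
        vstep <- protocol$step_levels[sw]
        i_ss <- gm_c * eval_boltzmann(vstep, vh_c, q, temperature_K) *
          (vstep - reversal)
        relax <- if (tau_relax <= 0) rep(1, length(tt))
        else 1 - exp(-tt / tau_relax)
        i <- i_hold + (i_ss - i_hold) * relax +
          rnorm(length(tt), 0, noise$trace_noise_sd)
        k <- k + 1L
        out[[k]] <- data.frame(cell_id = cell, sweep_id = sw, step_mV = vstep,
                               time_ms = tt, value_pA = i)
      }
    }
    res <- do.call(rbind, out)
    attr(res, "protocol") <- protocol
    class(res) <- c("sweep_set", "data.frame")
    res
  })
}

#' End-of-pulse current per sweep
#'
#' Mean current over the last fraction of each voltage step, the standard
#' amplitude measure for slowly relaxing currents.
#'
#' @param sweeps `sweep_set` from [gen_ikm_sweeps()].
#' @param tail_frac fraction of the step used, default the last 10%.
#' @return data.frame with `cell_id`, `step_mV`, `i_pA`.
#' @export
end_of_pulse <- function(sweeps, tail_frac = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  dur <- attr(sweeps, "protocol")$step_duration
  sel <- sweeps$time_ms >= (1 - tail_frac) * dur
  agg <- aggregate(value_pA ~ cell_id + step_mV, data = sweeps[sel, ], FUN = mean)
  names(agg)[names(agg) == "value_pA"] <- "i_pA"
  agg[order(agg$cell_id, agg$step_mV), ]
}

#' Generate a per-cell concentration-response table
#'
#' Per-cell responses follow a Hill curve with jittered `e_max` (lognormal)
#' and `ec50` (Gaussian), plus Gaussian response noise; the table is then
#' renormalized so the mean response at the top (normalizing) concentration
#' is 100%.
#'
#' @param concentrations tested concentrations, uM (> 0); the maximum is the
#'   normalizing concentration.
#' @param e_max,ec50,n_h Hill parameters of the underlying curve.
#' @param noise [noise_spec()]; `trace_noise_sd` is the response SD in
#'   percentage points, `cell_cv` the parameter jitter.
#' @param n_cells number of simulated cells.
#' @return data.frame (class `dose_response_table`) with columns `cell_id`,
#'   `conc_uM`, `response_pct`.
#' @export
gen_dose_response <- function(concentrations, e_max = 100, ec50 = 9.8,
                              n_h = 1, noise = noise_spec(), n_cells = 1) {
  if (!length(concentrations)) stop("concentration list must be non-empty")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  stopifnot(inherits(noise, "noise_spec"))
  with_stream(noise$seed, STREAM[["dose"]], {
    top <- max(concentrations)
    out <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      em_c <- e_max * rlnorm(1, -noise$cell_cv^2 / 2, noise$cell_cv)
      ec_c <- max(ec50 + rnorm(1, 0, noise$cell_cv * ec50), 1e-3)
      r <- eval_hill(concentrations, em_c, ec_c, n_h) +
        rnorm(length(concentrations), 0, noise$trace_noise_sd)
      out[[cell]] <- data.frame(cell_id = cell, conc_uM = concentrations,
                                response_pct = r)
    }
    res <- do.call(rbind, out)
    top_mean <- mean(res$response_pct[res$conc_uM == top])
    res$response_pct <- res$response_pct / top_mean * 100
    class(res) <- c("dose_response_table", "data.frame")
    res
  })
}

#' Generate a stochastic multi-channel telegraph trace
#'
#' Each channel is an independent two-state Markov chain with exponential
#' open/closed dwell times; the trace is the number of open channels times
#' the unitary amplitude, plus Gaussian noise.  Generated dwell sequences
#' are kept as an attribute for use as an idealization oracle.
#'
#' @param spec [channel_sim_spec()].
#' @param noise [noise_spec()]; if `trace_noise_sd` is 0 a default of
#'   0.15 x |unitary amplitude| is used so half-amplitude idealization is
#'   exercised realistically (pass an explicit 1e-12-ish value for a
#'   noiseless trace).
#' @param sample_interval sampling interval, ms; dwell means must be
#'   >= 5 x this so events are resolvable.
#' @return data.frame (class `channel_trace`) with `time_ms`, `value_pA`,
#'   plus attributes `level` (true open-channel count per sample),
#'   `unitary_amplitude`, `baseline` (0).
#' @export
gen_single_channel_trace <- function(spec, noise = noise_spec(),
                                     sample_interval = 0.1) {
  stopifnot(inherits(spec, "channel_sim_spec"), inherits(noise, "noise_spec"))
  p <- spec$open_probability
  if (p > 0 && p < 1 &&
      min(spec$mean_open_time, spec$mean_closed_time) < 5 * sample_interval)
    stop("unresolvable dwell times: dwell means must be >= 5 x sample_interval")
  sd_noise <- if (noise$trace_noise_sd > 0) noise$trace_noise_sd
  else 0.15 * abs(spec$unitary_amplitude)
  with_stream(noise$seed, STREAM[["channel"]], {
    nt <- floor(spec$duration / sample_interval) + 1L
    tt <- (seq_len(nt) - 1L) * sample_interval
    level <- integer(nt)
    for (ch in seq_len(spec$n_channels)) {
      if (p == 0) next
      if (p == 1) { level <- level + 1L; next }
      # stationary start, then alternate exponential dwells
      state <- runif(1) < p
      t_cur <- 0
      idx <- 1L
      while (t_cur < spec$duration) {
        dwell <- rexp(1, 1 / if (state) spec$mean_open_time else spec$mean_closed_time)
        t_next <- t_cur + dwell
        i_next <- min(nt, floor(t_next / sample_interval) + 1L)
        if (state && i_next > idx) level[idx:(i_next - 1L)] <-
            level[idx:(i_next - 1L)] + 1L
        idx <- i_next
        t_cur <- t_next
        state <- !state
      }
      if (state && idx <= nt) level[idx:nt] <- level[idx:nt] + 1L
    }
    value <- level * spec$unitary_amplitude + rnorm(nt, 0, sd_noise)
    res <- data.frame(time_ms = tt, value_pA = value)
    attr(res, "level") <- level
    attr(res, "unitary_amplitude") <- spec$unitary_amplitude
    attr(res, "baseline") <- 0
    class(res) <- c("channel_trace", "data.frame")
    res
  })
}

#' Default biphasic action-current waveform
#'
#' A brief spike-shaped transient: sharp downward lobe followed by a smaller
#' upward rebound, mimicking the capacitive current of an underlying action
#' potential in cell-attached voltage clamp.
#'
#' @param amplitude_pA depth of the downward lobe, pA (> 0).
#' @param width_ms total waveform support, ms.
#' @param sample_interval sampling interval, ms.
#' @return numeric vector of waveform samples (pA).
#' @export
action_current_waveform <- function(amplitude_pA = 40, width_ms = 6,
                                    sample_interval = 0.2) {
  tt <- seq(0, width_ms, by = sample_interval)
  t1 <- width_ms / 3
  down <- -amplitude_pA * exp(-((tt - t1) / (t1 / 2))^2)
  up <- 0.4 * amplitude_pA * exp(-((tt - 2 * t1) / t1)^2)
  down + up
}

#' Generate a Poisson train of action-current events
#'
#' Homogeneous Poisson event times over the duration; each event stamps the
#' biphasic waveform onto a noisy baseline.
#'
#' @param rate mean event rate, Hz (>= 0).
#' @param duration_s trace duration, seconds.
#' @param waveform waveform samples (pA), e.g. [action_current_waveform()].
#' @param noise [noise_spec()]; `trace_noise_sd` defaults to 2 pA when 0.
#' @param sample_interval sampling interval, ms.
#' @return data.frame (class `event_trace`) with `time_ms`, `value_pA`;
#'   attribute `event_times_s` holds the true event times.
#' @export
gen_action_current_train <- function(rate, duration_s,
                                     waveform = action_current_waveform(),
                                     noise = noise_spec(),
                                     sample_interval = 0.2) {
  if (rate < 0) stop("rate must be >= 0")
  stopifnot(inherits(noise, "noise_spec"))
  sd_noise <- if (noise$trace_noise_sd > 0) noise$trace_noise_sd else 2
  with_stream(noise$seed, STREAM[["train"]], {
    dur_ms <- duration_s * 1000
    nt <- floor(dur_ms / sample_interval) + 1L
    x <- rnorm(nt, 0, sd_noise)
    n_ev <- rpois(1, rate * duration_s)
    ev <- sort(runif(n_ev, 0, duration_s))
    for (t0 in ev) {
      i0 <- floor(t0 * 1000 / sample_interval) + 1L
      i1 <- min(nt, i0 + length(waveform) - 1L)
      x[i0:i1] <- x[i0:i1] + waveform[seq_len(i1 - i0 + 1L)]
    }
    res <- data.frame(time_ms = (seq_len(nt) - 1L) * sample_interval,
                      value_pA = x)
    attr(res, "event_times_s") <- ev
    class(res) <- c("event_trace", "data.frame")
    res
  })
}

#' Generate a single-channel amplitude-voltage table
#'
#' Ohmic unitary amplitudes `i = g * (V - reversal)` with optional Gaussian
#' noise, for conductance regression.
#'
#' @param conductance_pS unitary conductance, pS.
#' @param reversal reversal potential, mV.
#' @param potentials holding potentials, mV (>= 2 distinct values).
#' @param noise [noise_spec()]; `trace_noise_sd` is the amplitude SD in pA.
#' @return data.frame with `v_mV`, `i_pA`.
#' @export
gen_single_channel_iv <- function(conductance_pS, reversal = 0,
                                  potentials = seq(-60, 60, by = 20),
                                  noise = noise_spec()) {
  if (length(unique(potentials)) < 2)
    stop("need >= 2 distinct potentials")
  stopifnot(inherits(noise, "noise_spec"))
  with_stream(noise$seed, STREAM[["iv"]], {
    i <- conductance_pS / 1000 * (potentials - reversal) +
      rnorm(length(potentials), 0, noise$trace_noise_sd)
    data.frame(v_mV = potentials, i_pA = i)
  })
}
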