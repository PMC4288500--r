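# shared fixtures: quick simulation settings and independent fit oracles

quick_sim <- function(params = model_params(), duration = 3000, dt = 0.01,
                      ...) {
  simulate_neuron(params, sim_config(duration = duration, dt = dt,
                                     record_interval = 0.1), ...)
}

# coarse-to-fine grid-search oracle for the Hill fit: profiles e_max by
# linear least squares at each (ec50, n_h) grid point
hill_grid_oracle <- function(conc, y, ec50_range, nh_range, res = 0.01) {
  best <- c(ec50 = NA, n_h = NA, sse = Inf)
  sweep1 <- function(ec_grid, nh_grid) {
    for (ec in ec_grid) for (nh in nh_grid) {
      shape <- conc^nh / (ec^nh + conc^nh)
      em <- sum(shape * y) / sum(shape^2)
      sse <- sum((y - em * shape)^2)
      if (sse < best[["sse"]]) best <<- c(ec50 = ec, n_h = nh, sse = sse)
    }
  }
  sweep1(seq(ec50_range[1], ec50_range[2], length.out = 40),
         seq(nh_range[1], nh_range[2], length.out = 25))
  for (i in 1:3) {
    ec <- best[["ec50"]]; nh <- best[["n_h"]]
    wec <- diff(ec50_range) / 8^i; wnh <- diff(nh_range) / 8^i
    sweep1(seq(max(ec - wec, 1e-3), ec + wec, length.out = 25),
           seq(max(nh - wnh, 0.05), nh + wnh, length.out = 25))
  }
  best
}

# grid-search oracle for the Boltzmann fit (g_max profiled linearly)
boltzmann_grid_oracle <- function(v, g, vh_range, q_range) {
  vt <- thermal_voltage_mV()
  best <- c(v_half = NA, q = NA, sse = Inf)
  sweep1 <- function(vh_grid, q_grid) {
    for (vh in vh_grid) for (q in q_grid) {
      shape <- 1 / (1 + exp(-(v - vh) * q / vt))
      gm <- sum(shape * g) / sum(shape^2)
      sse <- sum((g - gm * shape)^2)
      if (sse < best[["sse"]]) best <<- c(v_half = vh, q = q, sse = sse)
    }
  }
  sweep1(seq(vh_range[1], vh_range[2], length.out = 50),
         seq(q_range[1], q_range[2], length.out = 30))
  for (i in 1:3) {
    vh <- best[["v_half"]]; q <- best[["q"]]
    sweep1(seq(vh - 4 / 8^(i - 1), vh + 4 / 8^(i - 1), length.out = 25),
           seq(max(q - 0.5 / 8^(i - 1), 0.05), q + 0.5 / 8^(i - 1),
               length.out = 25))
  }
  best
}

# O(n^2) brute-force burst segmentation reference
segment_bursts_bruteforce <- function(spike_times, gap_ms = 100) {
  st <- sort(spike_times)
  n <- length(st)
  if (!n) return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                            n_spikes = integer(0)))
  member <- rep(NA_integer_, n)
  b <- 0L
  for (i in seq_len(n)) {
    joined <- FALSE
    if (i > 1) for (j in seq_len(i - 1)) {
      if (abs(st[i] - st[j]) < gap_ms && all(st[seq(j, i)] |> diff() < gap_ms)) {
        member[i] <- member[j]; joined <- TRUE; break
      }
    }
    if (!joined) { b <- b + 1L; member[i] <- b }
  }
  do.call(rbind, lapply(split(st, member), function(s)
    data.frame(start_ms = min(s), end_ms = max(s), n_spikes = length(s))))
}
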