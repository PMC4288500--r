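#' Detect spikes as upward threshold crossings
#'
#' @param trace `sim_trace` or data.frame with `time_ms` and `V`.
#' @param threshold_mV crossing threshold, default 0 mV.
#' @param lockout_ms refractory lockout, default 2 ms.
#' @return numeric vector of spike times, ms.
#' @export
detect_spikes <- function(trace, threshold_mV = 0, lockout_ms = 2) {
  stopifnot(all(c("time_ms", "V") %in% names(trace)))
  up <- which(diff(trace$V > threshold_mV) == 1) + 1L
  tt <- trace$time_ms[up]
  if (!length(tt)) return(numeric(0))
  keep <- c(TRUE, diff(tt) >= lockout_ms)
  # sequential lockout
  out <- numeric(0)
  for (t in tt) if (!length(out) || t - tail(out, 1) >= lockout_ms)
    out <- c(out, t)
  out
}

#' Segment a spike train into bursts
#'
#' Maximal runs of spikes whose consecutive inter-spike intervals are below
#' `gap_ms`; singleton spikes count as one-spike bursts.
#'
#' @param spike_times spike times, ms.
#' @param gap_ms burst-terminating gap, ms (> 0), default 100.
#' @return data.frame with `start_ms`, `end_ms`, `n_spikes` (possibly 0 rows).
#' @export
segment_bursts <- function(spike_times, gap_ms = 100) {
  if (gap_ms <= 0) stop("gap_ms must be > 0")
  if (!length(spike_times))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      n_spikes = integer(0)))
  st <- sort(spike_times)
  brk <- which(diff(st) >= gap_ms)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(st))
  data.frame(start_ms = st[starts], end_ms = st[ends],
             n_spikes = ends - starts + 1L)
}

#' After-hyperpolarization depth between bursts
#'
#' Minimum membrane potential over all interburst windows (from the end of
#' one burst to the start of the next).
#'
#' @param trace data.frame with `time_ms`, `V`.
#' @param bursts burst table from [segment_bursts()] with >= 2 rows.
#' @return list with `ahp_min_mV` and `window` count; with fewer than two
#'   bursts the result is flagged undefined (`ahp_min_mV = NA`).
#' @export
ahp_depth <- function(trace, bursts) {
  stopifnot(all(c("time_ms", "V") %in% names(trace)))
  if (nrow(bursts) < 2)
    return(list(ahp_min_mV = NA_real_, n_windows = 0L,
                flag = "undefined: fewer than 2 bursts"))
  vmin <- Inf
  for (i in seq_len(nrow(bursts) - 1L)) {
    sel <- trace$time_ms > bursts$end_ms[i] &
      trace$time_ms < bursts$start_ms[i + 1L]
    if (any(sel)) vmin <- min(vmin, min(trace$V[sel]))
  }
  list(ahp_min_mV = vmin, n_windows = nrow(bursts) - 1L, flag = NULL)
}

#' Full burst metrics of a voltage trace
#'
#' Spike detection, burst segmentation, intraburst rate
#' (`(spikes - 1) / burst duration` averaged over multi-spike bursts),
#' mean interburst interval, and interburst AHP depth.
#'
#' @param trace data.frame with `time_ms`, `V`.
#' @param threshold_mV spike threshold, mV.
#' @param gap_ms burst gap, ms.
#' @param discard_ms initial transient to discard, ms.
#' @return list of class `burst_metrics`.
#' @export
burst_metrics <- function(trace, threshold_mV = 0, gap_ms = 100,
                          discard_ms = 0) {
  tr <- trace[trace$time_ms >= discard_ms, , drop = FALSE]
  sp <- detect_spikes(tr, threshold_mV)
  bursts <- segment_bursts(sp, gap_ms)
  multi <- bursts[bursts$n_spikes > 1, , drop = FALSE]
  intra <- if (nrow(multi))
    mean((multi$n_spikes - 1) / ((multi$end_ms - multi$start_ms) / 1000))
  else NA_real_
  ibi <- if (nrow(bursts) >= 2)
    mean(bursts$start_ms[-1] - bursts$end_ms[-nrow(bursts)])
  else NA_real_
  ahp <- ahp_depth(tr, bursts)
  structure(list(spike_times = sp, bursts = bursts,
                 spikes_per_burst = if (nrow(bursts)) mean(bursts$n_spikes) else 0,
                 intraburst_rate_Hz = intra, interburst_interval_ms = ibi,
                 ahp_min_mV = ahp$ahp_min_mV, ahp_flag = ahp$flag),
            class = "burst_metrics")
}

#' Fold change in peak current amplitude between two simulations
#'
#' Ratio of peak absolute current (condition b over condition a) over the
#' analysis window.
#'
#' @param trace_a,trace_b `sim_trace` objects that recorded `current`.
#' @param current current name, e.g. `"I_M"`.
#' @param from_ms start of the analysis window (discards the stimulus
#'   transient), default 300 ms.
#' @return dimensionless ratio.
#' @export
fold_change <- function(trace_a, trace_b, current, from_ms = 300) {
  for (tr in list(trace_a, trace_b))
    if (!current %in% names(tr)) stop("current '", current, "' not recorded")
  pa <- max(abs(trace_a[[current]][trace_a$time_ms >= from_ms]))
  pb <- max(abs(trace_b[[current]][trace_b$time_ms >= from_ms]))
  if (pa == 0) stop("zero peak amplitude in denominator trace")
  pb / pa
}
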