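#' Fit a Gaussian mixture to the all-points amplitude histogram
#'
#' Bins the trace into an all-points histogram and fits a sum of `n_levels`
#' Gaussians by least squares (the multigaussian adjustment used to read off
#' single-channel current levels).  The unitary amplitude is the mean spacing
#' of adjacent level means; weights are normalized to sum to 1.
#'
#' @param trace numeric vector of samples, or a data.frame with `value_pA`.
#' @param n_levels number of amplitude levels to fit (>= 2).
#' @param bins number of histogram bins.
#' @return list of class `amp_hist_fit`: `means` (sorted), `sds`, `weights`,
#'   `unitary_amplitude`, `baseline` (mean of the heaviest level),
#'   `convergence` (flag list; fewer apparent modes than `n_levels` raises a
#'   flag).
#' @export
amplitude_histogram_fit <- function(trace, n_levels = 2, bins = 200) {
  x <- if (is.data.frame(trace)) trace$value_pA else as.numeric(trace)
  if (length(x) < 1000) stop("trace must have >= 1000 samples")
  if (n_levels < 2) stop("n_levels must be >= 2")
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  mids <- h$mids
  dens <- h$density
  # initialize means from quantile spread via kmeans on the samples
  km <- tryCatch(stats::kmeans(x, centers = n_levels, nstart = 5,
                               iter.max = 50),
                 error = function(e) NULL)
  mu0 <- if (is.null(km)) quantile(x, probs = seq(0.1, 0.9, length.out = n_levels))
  else sort(km$centers[, 1])
  sd0 <- rep(mad(x) / 2 + 1e-6, n_levels)
  w0 <- if (is.null(km)) rep(1 / n_levels, n_levels)
  else tabulate(km$cluster, n_levels)[order(km$centers[, 1])] / length(x)

  mixdens <- function(par) {
    mu <- par[seq_len(n_levels)]
    sig <- exp(par[n_levels + seq_len(n_levels)])
    lw <- par[2 * n_levels + seq_len(n_levels)]
    w <- exp(lw) / sum(exp(lw))
    rowSums(sapply(seq_len(n_levels),
                   function(j) w[j] * dnorm(mids, mu[j], sig[j])))
  }
  par0 <- c(mu0, log(sd0), log(w0 + 1e-9))
  obj <- function(par) sum((mixdens(par) - dens)^2)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  mu <- opt$par[seq_len(n_levels)]
  sig <- exp(opt$par[n_levels + seq_len(n_levels)])
  w <- exp(opt$par[2 * n_levels + seq_len(n_levels)])
  w <- w / sum(w)
  ord <- order(mu)
  mu <- unname(mu[ord]); sig <- unname(sig[ord]); w <- unname(w[ord])
  spacing <- diff(mu)
  # modes closer than their widths indicate fewer apparent modes than asked
  distinct <- all(abs(spacing) > (sig[-n_levels] + sig[-1]) / 2)
  flag <- if (opt$convergence != 0)
    fit_flag(FALSE, "optimizer did not converge")
  else if (!distinct)
    fit_flag(FALSE, sprintf("fewer than %d distinct modes apparent", n_levels))
  else fit_flag(TRUE)
  structure(list(means = mu, sds = sig, weights = w,
                 unitary_amplitude = mean(spacing),
                 baseline = mu[which.max(w)], convergence = flag),
            class = "amp_hist_fit")
}

#' Idealize a single-channel trace by half-amplitude threshold
#'
#' Each sample is assigned the level `round((x - baseline)/unitary)` clamped
#' at >= 0 (downward-deflecting openings are handled by a negative
#' `unitary`); runs shorter than `min_samples` are merged into their
#' neighbors (censored as dead time).
#'
#' @param trace numeric vector or data.frame with `value_pA` and `time_ms`.
#' @param baseline closed-level current, pA.
#' @param unitary unitary current amplitude, pA (non-zero; sign gives the
#'   deflection direction).
#' @param sample_interval sampling interval, ms (taken from `time_ms` when
#'   present).
#' @param min_samples minimum resolvable dwell in samples (default 2).
#' @return list of class `idealized_trace`: data.frame `segments`
#'   (`start_ms`, `duration_ms`, `level`), plus `unitary_amplitude`,
#'   `baseline`, `total_ms`.
#' @export
idealize_trace <- function(trace, baseline, unitary, sample_interval = NULL,
                           min_samples = 2) {
  x <- if (is.data.frame(trace)) trace$value_pA else as.numeric(trace)
  if (unitary == 0) stop("unitary amplitude must be non-zero")
  if (is.null(sample_interval)) {
    if (is.data.frame(trace) && "time_ms" %in% names(trace) && nrow(trace) > 1)
      sample_interval <- trace$time_ms[2] - trace$time_ms[1]
    else stop("sample_interval required when trace has no time column")
  }
  # sign normalization: work in units of the (possibly negative) unitary step
  lev <- pmax(0L, as.integer(round((x - baseline) / unitary)))
  # merge short runs into neighbors, iterating until stable
  repeat {
    r <- rle(lev)
    short <- which(r$lengths < min_samples)
    short <- short[!(short %in% c(1L, length(r$lengths))) |
                     length(r$lengths) == 1L]
    if (!length(short)) break
    i <- short[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    lev <- inverse.rle(r)
  }
  r <- rle(lev)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  segments <- data.frame(start_ms = starts * sample_interval,
                         duration_ms = r$lengths * sample_interval,
                         level = r$values)
  structure(list(segments = segments, unitary_amplitude = unitary,
                 baseline = baseline,
                 total_ms = length(lev) * sample_interval),
            class = "idealized_trace")
}

#' NPo from an idealized trace
#'
#' `NPo = sum(level_i * duration_i) / total duration`: the time-averaged
#' number of simultaneously open channels.  For a single channel this is the
#' open probability Po in `[0, 1]`.
#'
#' @param ideal `idealized_trace` from [idealize_trace()].
#' @return NPo, dimensionless.
#' @export
estimate_npo <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  seg <- ideal$segments
  if (!nrow(seg)) stop("empty idealization")
  sum(seg$level * seg$duration_ms) / ideal$total_ms
}

#' Detect action currents as downward threshold crossings
#'
#' The baseline and its robust SD are estimated by median and MAD; events
#' are excursions below `median - k_sd * MAD-SD`, reported at their peak
#' (minimum) time, with a refractory lockout.
#'
#' @param trace data.frame with `time_ms`, `value_pA` (>= 10 s long for
#'   stable baseline statistics).
#' @param k_sd detection threshold in robust SDs (> 0), default 6.
#' @param lockout_ms refractory lockout, ms, default 20.
#' @return list of class `event_train`: `event_times_s` (strictly
#'   increasing), `duration_s`.
#' @export
detect_action_currents <- function(trace, k_sd = 6, lockout_ms = 20) {
  stopifnot(is.data.frame(trace), all(c("time_ms", "value_pA") %in% names(trace)))
  if (k_sd <= 0) stop("k_sd must be > 0")
  dur_s <- (max(trace$time_ms) - min(trace$time_ms)) / 1000
  if (dur_s < 10) stop("trace must be >= 10 s for stable baseline statistics")
  x <- trace$value_pA
  base <- median(x)
  s <- mad(x)
  thr <- base - k_sd * s
  below <- x < thr
  if (!any(below)) return(structure(list(event_times_s = numeric(0),
                                         duration_s = dur_s),
                                    class = "event_train"))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ev <- numeric(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    pk <- seg[which.min(x[seg])]
    tpk <- trace$time_ms[pk]
    if (!length(ev) || tpk - tail(ev, 1) >= lockout_ms) ev <- c(ev, tpk)
  }
  structure(list(event_times_s = ev / 1000, duration_s = dur_s),
            class = "event_train")
}

#' Event-train constructor
#'
#' @param event_times_s strictly increasing event times, seconds, within
#'   `[0, duration_s]`.
#' @param duration_s recording duration, seconds (> 0).
#' @return list of class `event_train`.
#' @export
event_train <- function(event_times_s, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (length(event_times_s) &&
      (is.unsorted(event_times_s, strictly = TRUE) ||
       min(event_times_s) < 0 || max(event_times_s) > duration_s))
    stop("event times must be strictly increasing within [0, duration]")
  structure(list(event_times_s = event_times_s, duration_s = duration_s),
            class = "event_train")
}

#' Mean firing frequency of an event train
#'
#' @param train `event_train`.
#' @return events per second, Hz.
#' @examples
#' firing_frequency(event_train(seq(0.5, 99.5, length.out = 121), 100))  # 1.21
#' @export
firing_frequency <- function(train) {
  stopifnot(inherits(train, "event_train"))
  if (train$duration_s <= 0) stop("duration must be > 0")
  length(train$event_times_s) / train$duration_s
}
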