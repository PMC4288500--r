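#' Equilibria of the fast subsystem at frozen slow gates
#'
#' The fast subsystem sets every gating variable to its voltage steady state
#' except the two slow gates, `n` (T-type Ca2+ activation) and `o` (KCa
#' activation), which are treated as parameters; intracellular Ca2+ is held
#' fixed (cycle-average convention).  Roots of the quasi-steady current
#' balance F(V) = 0 are located by sign-change bracketing on [-120, 60] mV
#' and bisection; stability is read from the sign of dF/dV.
#'
#' @param params [model_params()].
#' @param n frozen T-type activation in `[0, 1]`.
#' @param o frozen KCa activation in `[0, 1]`.
#' @param ca fixed intracellular Ca2+, uM.
#' @param kin kinetics constants.
#' @param v_range search interval, mV.
#' @param grid_mV bracketing grid spacing, mV.
#' @param tol_mV bisection tolerance, mV.
#' @return data.frame with `V_mV` and `stable` (logical); zero rows when no
#'   equilibrium exists.
#' @export
fast_subsystem_equilibria <- function(params, n, o, ca = 1,
                                      kin = kinetics_constants(),
                                      v_range = c(-120, 60), grid_mV = 0.5,
                                      tol_mV = 1e-6) {
  stopifnot(n >= 0, n <= 1, o >= 0, o <= 1)
  p <- params
  p[["i_app"]] <- 0
  vg <- seq(v_range[1], v_range[2], by = grid_mV)
  Fv <- fast_balance_cpp(vg, p, kin, n, o, ca)
  idx <- which(diff(sign(Fv)) != 0)
  if (!length(idx))
    return(data.frame(V_mV = numeric(0), stable = logical(0)))
  roots <- vapply(idx, function(i) {
    lo <- vg[i]; hi <- vg[i + 1]
    flo <- Fv[i]
    while (hi - lo > tol_mV) {
      mid <- (lo + hi) / 2
      fm <- fast_balance_cpp(mid, p, kin, n, o, ca)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  # an exact zero on a grid point shows up as two adjacent sign changes
  roots <- roots[c(TRUE, diff(roots) > 10 * tol_mV)]
  dF <- vapply(roots, function(v) {
    h <- 1e-4
    diff(fast_balance_cpp(c(v - h, v + h), p, kin, n, o, ca)) / (2 * h)
  }, numeric(1))
  data.frame(V_mV = roots, stable = dF < 0)
}

has_stable_rest <- function(params, n, o, ca, kin, v_rest_max = -45, ...) {
  eq <- fast_subsystem_equilibria(params, n, o, ca, kin, ...)
  any(eq$stable & eq$V_mV <= v_rest_max)
}

#' Saddle-node boundary of the fast subsystem on the n-o plane
#'
#' For each frozen KCa activation `o`, finds the T-type activation `n*` at
#' which the stable hyperpolarized rest point of the fast subsystem is lost
#' (the saddle-node fold where two equilibria coalesce): below the curve the
#' neuron is silent, above it the fast subsystem fires repetitively.  `n*`
#' is found by bisection on `n` with the existence of a stable rest as the
#' indicator.  Raising `g_M` or `g_KCa` shifts the curve upward (more
#' depolarizing drive is needed to fire).
#'
#' @param params [model_params()].
#' @param o_grid KCa activation values at which to compute the fold.
#' @param ca fixed Ca2+ (uM); `NULL` computes the cycle average of a default
#'   3 s simulation of `params`.
#' @param kin kinetics constants.
#' @param tol bisection tolerance in `n`.
#' @param v_rest_max rest points must lie below this voltage (mV).
#' @return data.frame of class `nullcline_curve` with columns `o` and `n`
#'   (fold location; `NA` where no fold exists in `[0, 1]`, such points are
#'   dropped), plus attribute `ca`.
#' @export
compute_nullcline <- function(params, o_grid = seq(0.05, 0.95, by = 0.05),
                              ca = NULL, kin = kinetics_constants(),
                              tol = 1e-6, v_rest_max = -45) {
  if (length(o_grid) < 2) stop("o_grid must have >= 2 points")
  if (is.null(ca)) ca <- cycle_average_ca(params, kin)
  nstar <- vapply(o_grid, function(o) {
    lo <- 0; hi <- 1
    if (!has_stable_rest(params, lo, o, ca, kin, v_rest_max)) return(NA_real_)
    if (has_stable_rest(params, hi, o, ca, kin, v_rest_max)) return(NA_real_)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (has_stable_rest(params, mid, o, ca, kin, v_rest_max)) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  keep <- !is.na(nstar)
  res <- data.frame(o = o_grid[keep], n = nstar[keep])
  attr(res, "ca") <- ca
  class(res) <- c("nullcline_curve", "data.frame")
  res
}

#' Cycle-average intracellular Ca2+ of a burst simulation
#'
#' @param params [model_params()].
#' @param kin kinetics constants.
#' @param duration,dt simulation settings, ms.
#' @param discard_ms transient to discard.
#' @return mean Ca2+ (uM) over the retained window.
#' @export
cycle_average_ca <- function(params, kin = kinetics_constants(),
                             duration = 3000, dt = 0.01, discard_ms = 500) {
  tr <- simulate_neuron(params, sim_config(duration = duration, dt = dt,
                                           record_interval = 0.5),
                        kin = kin)
  mean(tr$ca[tr$time_ms >= discard_ms])
}

#' Project a burst trajectory onto the n-o plane
#'
#' Extracts one steady-state burst cycle (delimited by successive minima of
#' `o`, after discarding a transient) and returns it as an ordered closed
#' loop with its shoelace area.
#'
#' @param trace `sim_trace` containing gates `n` and `o`.
#' @param discard_ms transient to discard, ms.
#' @return list of class `trajectory_loop`: data.frame `points` (`n`, `o`),
#'   `area`, `flag` (`NULL`, or a message when no full cycle was found; the
#'   loop then degenerates to the final point with area 0).
#' @export
project_trajectory <- function(trace, discard_ms = 500) {
  stopifnot(all(c("time_ms", "n", "o") %in% names(trace)))
  tr <- trace[trace$time_ms >= discard_ms, , drop = FALSE]
  o <- tr$o
  # cycle delimiters: the minimum of o within each low excursion of o
  olow <- min(o) + 0.2 * diff(range(o))
  r <- rle(o < olow)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  lo <- vapply(which(r$values), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.min(o[seg])]
  }, integer(1))
  if (diff(range(o)) < 1e-6 || length(lo) < 2) {
    pt <- tr[nrow(tr), c("n", "o")]
    return(structure(list(points = pt, area = 0,
                          flag = "no periodic cycle detected"),
                     class = "trajectory_loop"))
  }
  i0 <- lo[length(lo) - 1L]
  i1 <- lo[length(lo)]
  pts <- tr[i0:i1, c("n", "o")]
  structure(list(points = pts, area = shoelace_area(pts$n, pts$o),
                 flag = NULL),
            class = "trajectory_loop")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Mean vertical shift between two saddle-node boundary curves
#'
#' Interpolates both curves on their shared `o` range and returns the mean
#' difference in fold location `n` (curve `b` minus curve `a`): positive
#' means `b` lies above `a`, i.e. the firing threshold has moved up.
#'
#' @param a,b `nullcline_curve` objects.
#' @param n_interp number of interpolation points.
#' @return mean shift in `n` over the shared `o` range.
#' @export
nullcline_shift <- function(a, b, n_interp = 101) {
  stopifnot(inherits(a, "nullcline_curve"), inherits(b, "nullcline_curve"))
  lo <- max(min(a$o), min(b$o))
  hi <- min(max(a$o), max(b$o))
  if (lo >= hi) stop("curves have disjoint o ranges")
  og <- seq(lo, hi, length.out = n_interp)
  na <- approx(a$o, a$n, xout = og)$y
  nb <- approx(b$o, b$n, xout = og)$y
  mean(nb - na)
}
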