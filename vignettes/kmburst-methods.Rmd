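---
title: "Methods: channel pharmacology fits and the CA3 burst model"
author: "kmburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel pharmacology fits and the CA3 burst model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmburst)
```

## What the package models

Flavonoid openers of M-type (Kv7/KCNQ) and large-conductance
Ca^2+^-activated (BK) K^+^ channels act on two time scales at once: they
shift the voltage-activation of a slow subthreshold K^+^ current, and they
raise the open probability of single channels.  Both effects converge on one
physiological question — how does raising `g_M` and `g_KCa` reshape burst
firing in a central neuron?  The package covers the full quantitative chain:

1. **Synthetic recordings** (`gen_ikm_sweeps()`, `gen_dose_response()`,
   `gen_single_channel_trace()`, `gen_action_current_train()`,
   `gen_single_channel_iv()`): seeded generators with the statistical
   structure the downstream analyses assume.
2. **Curve fits** (`fit_hill()`, `fit_boltzmann()`, `conductance_slope()`,
   `single_channel_conductance()`).
3. **Event analysis** (`amplitude_histogram_fit()`, `idealize_trace()`,
   `estimate_npo()`, `detect_action_currents()`).
4. **A conductance-based burst model** (`simulate_neuron()`) with burst
   metrics (`burst_metrics()`) and a fast–slow decomposition
   (`compute_nullcline()`, `project_trajectory()`).

## Concentration–response and voltage–activation fits

The Hill response is evaluated in the standard form
$y = E_{\max} C^{n_H} / (EC_{50}^{n_H} + C^{n_H})$.  A variant with an
un-exponentiated denominator term ($EC_{50} + C^{n_H}$) circulates in print;
it is dimensionally inconsistent for $n_H \ne 1$ and is provided only behind
`paper_form = TRUE` for comparison.  The fits are ordinary nonlinear least
squares (Levenberg–Marquardt via **minpack.lm**) with data-driven starts:
`ec50` at the concentration nearest half-maximal mean response, `n_h` at 1,
`v_half` at the voltage of half-range conductance, `q` at 2 elementary
charges.  Standard errors come from the curvature of the objective at the
optimum.  Non-convergence and degenerate inputs (flat responses) are flagged
in the returned object, never silently.

Voltage activation uses the two-state Boltzmann
$G/G_{\max} = 1/(1+\exp[-(V-V_{1/2})qF/RT])$ with the apparent gating charge
$q$ in elementary charges and a default temperature of 295 K (room-temperature
recordings, $RT/F = 25.4$ mV).  Whole-cell chord conductance is the OLS slope
of end-of-pulse current on voltage inside a closed window (default
$-30..-10$ mV), reported in nS; single-channel conductance is the regression
slope of unitary amplitudes on holding potential, in pS.

## The synthetic-data generators

All randomness flows from one integer seed through a named stream per
generator (fixed offsets), so identical seeds give bit-identical tables and
the caller's RNG state is never disturbed.  Calibration choices, made once:

* **Whole-cell sweeps** relax mono-exponentially to the Boltzmann steady
  state with `tau_relax = 150` ms, typical of Kv7 gating; the end-of-pulse
  measure (mean over the last 10 % of the step) is insensitive to this value.
* **Cell-to-cell variability** is lognormal on amplitude-like parameters
  (`G_max`, `E_max`) and Gaussian on location-like parameters (`V_half`,
  `EC50`), both scaled by `cell_cv`.  The defaults used in the shipped
  scenarios (`cell_cv = 0.12`, response noise 5 percentage points) are
  back-calculated from the standard errors reported for 7–13-cell data sets
  in this preparation (e.g. an $EC_{50}$ SEM of 0.4 µM at $n \approx 10$
  implies a per-cell SD near 1.2 µM).
* **Single-channel records** are sums of independent two-state Markov
  chains with exponential dwells; the default trace noise is
  0.15 × unitary amplitude, low enough for reliable half-amplitude
  idealization yet high enough to exercise it.  The generated state path is
  attached to the trace so idealization can be tested against the exact
  truth.
* **Action-current trains** are homogeneous Poisson processes stamping a
  biphasic (sharp downward, small rebound) waveform on Gaussian baseline
  noise; default SNR is about 20.

What these generators deliberately do **not** emulate: capacitive
transients, series-resistance and liquid-junction artifacts, baseline drift,
line noise, filter ringing, or channel subconductance states.  Passing tests
therefore demonstrate correctness of the estimators under the model's own
assumptions, not robustness to every artifact of real recordings.

## Event analysis

Amplitude levels are read from a least-squares fit of a Gaussian mixture to
the all-points histogram; the baseline is the heaviest mode (openings bias a
plain mean), and the unitary amplitude is the mean spacing of adjacent level
means.  Idealization uses the field-standard half-amplitude threshold: each
sample maps to `round((x - baseline)/unitary)`, clamped at zero, with a
two-sample dead time (shorter flickers are censored into their neighbours).
Downward-deflecting cell-attached openings are handled by a negative
unitary amplitude.  `NPo` is the duration-weighted mean level; for one
channel it is the open probability.

Action currents are detected as excursions below a robust threshold
(median − `k_sd` × MAD-based SD, default `k_sd = 6`) with a 20 ms lockout
chosen from the ~1 Hz firing rates of this preparation; both are
configurable because the source analyses do not state them.

## The burst model

The membrane equation is
$C_m \dot V = -(I_{Na}+I_{CaT}+I_{CaL}+I_{CaN}+I_{KDR}+I_A+I_M+I_{KCa}+I_{AHP}+I_{Leak}) + I_{app}$,
integrated by explicit Euler at $dt = 0.001$ ms (a classical RK4 integrator
is available for step-size checks).  `I_M` is included in the K^+^ sum: the
parameter table provides `g_M` and the study's simulations plot the
M-current, so its omission from the printed current list is read as
typographical.

**Units.** The published parameter table mixes unit rows.  One coherent
per-area system is used: $C_m = 1\,\mu F/cm^2$, every conductance magnitude
read as mS/cm^2^, and reversals in mV.  The Ca^2+^ conductance rows are
tabulated in different units from the K^+^ rows, consistent with
permeability-style magnitudes; accordingly the Ca^2+^ currents use a
constant-field (GHK) driving term with $[Ca]_o = 2$ mM, normalized by an
explicit constant `ca_drive` so that the printed magnitudes yield
physiological current densities.

**Applied current.** The printed 0.004 mA stimulus is read as
0.004 mA/cm^2^ delivered as a brief pulse (default 50 ms starting at 50 ms).
A continuous current of that size is incompatible with the reported
interburst potentials: with every K^+^ conductance of the table saturated,
the maximum outward current at −81 mV is about 0.75 µA/cm^2^, far below
4 µA/cm^2^, so no gating state could hold the membrane there under constant
injection.  With the brief-pulse reading the model bursts endogenously and
the reported afterhyperpolarizations emerge.  A consequence worth noting:
the rest point of the full system is unstable (the slow subsystem supports a
limit cycle), so `resting_state()` on the default parameters returns its
flagged-oscillatory branch rather than a fixed point.

**Kinetics.** The source model's rate functions are not printed and its
Markov Na^+^ scheme is replaced by a standard HH $m^3h$ description (the
state-model slot would be the natural extension point).  The package
therefore pins one concrete, fully documented set in
`kinetics_constants()`:

* fast spiking: $m^3h$ Na^+^ and $n^4$ delayed rectifier.  With the table's
  small $g_{Na}:g_{KDR}$ ratio, spike repolarization leans on steep Na^+^
  inactivation; the $h$ time constant is a Gaussian bell centred near spike
  threshold so inactivation cannot equilibrate during the interspike
  passage — the arrangement that makes the depolarized fixed point of the
  fast subsystem unstable and keeps the burst spiking instead of stalling
  on a plateau;
* a slow autocatalytic T-type activation gate `n` (no inactivation gate;
  fast deactivation when hyperpolarized, slow build-up when depolarized),
  which paces the interburst depolarization;
* a slow Ca^2+^-gated KCa activation gate `o` (Hill function of the Ca^2+^
  pool, $\tau_o = 120$ ms) providing the negative feedback that terminates
  bursts and sets the interburst afterhyperpolarization;
* a Boltzmann M-gate `w` ($V_{1/2} = -28$ mV, $\tau_w = 200$ ms) and a very
  slow Ca^2+^-gated AHP gate;
* a single well-mixed Ca^2+^ pool,
  $\dot{[Ca]} = -k\,I_{Ca} - ([Ca]-[Ca]_{rest})/\tau_{Ca}$.

Calibration targeted the study's regime under the table's conductances:
repetitive bursting at baseline, fewer spikes per burst as `g_M` rises,
interburst minima near −81 mV (`g_M` doubled) and −85 mV (both doubled),
and a ~1.5-fold rise in peak `I_M` when `g_M` doubles within the full
modulation.  All constants live in one place and every one can be
overridden.

**Numerical behaviour.** Gate variables remain in [0, 1] at the default
step; every recorded step satisfies the membrane-equation residual to
10^-6^ of the largest term; and the Euler trajectory agrees with the RK4
reference to well under 1 mV through the stimulated burst.  Beyond the first
*endogenous* ignition (~0.9 s in the default run) any two integrators
diverge visibly: square-wave ignition is a slow saddle passage that
amplifies numerical phase error exponentially, so late spikes shift by
milliseconds under step halving and pointwise voltage differences reach
spike amplitude.  This is a property of the dynamics, not of the
integrator; convergence statements are therefore made for spike *counts*
and burst *metrics* (robust) and for pointwise voltage only up to the first
endogenous ignition.

## Burst metrics

Spikes are upward crossings of 0 mV with a 2 ms lockout; bursts are maximal
spike runs with inter-spike intervals under 100 ms.  Both defaults are
justified by the simulated waveforms' clean time-scale separation
(intraburst intervals of tens of ms against interburst gaps of hundreds)
and are configurable.  The afterhyperpolarization is measured between
bursts — the minimum membrane potential over interburst windows — matching
how the interburst hyperpolarization is quoted; with fewer than two bursts
it is flagged undefined.  Both "intraburst rate" (spikes−1 over burst
duration, averaged over multi-spike bursts) and the interburst interval are
reported.

## Fast–slow decomposition

Freezing the two slow gates turns the remaining equations into the *fast
subsystem*: all other gates sit at their voltage steady states and the
Ca^2+^ pool is held at its cycle average (its treatment is not specified by
the source; the cycle-average convention is this package's choice).
Equilibria are roots of the quasi-steady current balance, located by
sign-change bracketing plus bisection to 10^-6^ mV — derivative-free and
robust near folds — with stability from the local slope.

The saddle-node boundary is parameterized as $n^*(o)$: for each KCa
activation level $o$, the minimum T-type drive $n$ at which the stable
hyperpolarized rest disappears.  This orientation is the one under which
the study's qualitative claims are internally consistent: raising `g_M`
shifts the boundary *upward* (more depolarizing drive needed to fire) with
little change in the burst trajectory, raising both conductances shifts it
further and compresses the trajectory loop.  Parameterizing the fold as
$o(n)$ instead would make the same physics read as a *downward* shift,
because extra K^+^ conductance lowers the $o$ at which rest is lost.  The
burst loop is one cycle of $(n(t), o(t))$ delimited by successive minima of
$o$, with the shoelace area as its size; near the fold the fast subsystem
is bistable (the hallmark of square-wave bursting), so boundary-straddling
checks start from the resting branch.

## Problem sizes used by the shipped tests

Unit tests run the model at $dt = 0.01$ ms for 2.5–5 s windows, where burst
counts and metrics are already converged; the headline quantities
(afterhyperpolarization depths, fold change) are computed at the protocol
step of $dt = 0.001$ ms over 3 s.  Stochastic recoveries use 200 synthetic
cells for the concentration–response fit, 60 s telegraph records, and a
100 s Poisson train — the sizes at which the estimators' sampling error
matches the tolerances quoted for them.

## Known limitations

* The Na^+^ current is HH-style, not the Markov scheme of the source
  model; kinetics are this package's own calibrated set, so agreement with
  the source is expected at the level of regimes and reported summary
  quantities, not voltage traces.
* Single compartment; no dendrites, synapses, channel noise, or
  temperature scaling.
* No hidden-Markov dwell-time modelling or missed-event correction in the
  single-channel analysis; the half-amplitude threshold with a two-sample
  dead time is the stated estimator.
* The hierarchical structure of multi-cell data is not modelled: fits pool
  cells rather than fitting per-cell curves with random effects.
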