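#' Physical constants used throughout the package
#'
#' Faraday's constant, the gas constant, and the default recording
#' temperature (room temperature).  `RT/F` at 295 K is 25.43 mV.
#' @keywords internal
#' @name physical-constants
NULL

FARADAY <- 96485.332   # C / mol
GAS_R <- 8.31446       # J / mol / K
DEFAULT_TEMP_K <- 295  # room temperature, 20-25 C

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_K absolute temperature in kelvin.
#' @return RT/F in mV.
#' @examples
#' thermal_voltage_mV(295)  # ~25.43 mV
#' @export
thermal_voltage_mV <- function(temperature_K = DEFAULT_TEMP_K) {
  1000 * GAS_R * temperature_K / FARADAY
}

#' Default membrane parameters of the CA3 burst model
#'
#' Maximal conductances (mS/cm^2), reversal potentials (mV), membrane
#' capacitance (uF/cm^2) and applied current for the single-compartment
#' CA3 pyramidal-neuron model.  The printed parameter table the model is
#' built around mixes units across rows; here one coherent per-area system
#' is used: all conductance magnitudes are read as mS/cm^2, Cm = 1 uF/cm^2,
#' and the 0.004 "mA" applied current is read as 0.004 mA/cm^2 delivered as
#' a brief triggering pulse (see `stim_start`/`stim_dur`, ms).  With the
#' Table defaults the model fires repetitive bursts; `g_M` and `g_KCa` are
#' the knobs scaled to mimic pharmacological channel activation.
#'
#' @param ... name = value overrides of any default parameter.
#' @return named numeric vector of class `model_params`.
#' @examples
#' p <- model_params(g_m = 0.04, g_kca = 0.1)
#' p[["g_m"]]
#' @export
model_params <- function(...) {
  p <- c(
    cm = 1,            # uF/cm^2
    g_na = 2,          # mS/cm^2, fast Na+
    g_cat = 0.45,      # T-type Ca2+
    g_cal = 0.0025,    # L-type Ca2+
    g_can = 0.0025,    # N-type Ca2+
    g_kdr = 0.08,      # delayed rectifier K+
    g_a = 0.1,         # A-type K+
    g_m = 0.02,        # M-type K+ (Kv7)
    g_kca = 0.05,      # Ca2+-activated K+ (BK-like)
    g_kahp = 0.0018,   # slow AHP K+
    g_leak = 0.0167,   # leak
    i_app = 4,         # uA/cm^2 (0.004 mA/cm^2), brief pulse
    stim_start = 50,   # ms
    stim_dur = 50,     # ms
    v_na = 50,         # mV
    v_k = -91,         # mV
    v_leak = -65       # mV
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown model parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- unlist(ov)
  }
  if (any(!is.finite(p))) stop("model parameters must be finite")
  gpos <- grep("^g_|^cm$", names(p))
  if (any(p[gpos] < 0)) stop("conductances and capacitance must be >= 0")
  class(p) <- c("model_params", "numeric")
  p
}

#' Kinetic rate-function constants of the CA3 burst model
#'
#' One pinned set of Hodgkin-Huxley-style rate constants for every gating
#' variable of the burst model, so the model is fully self-contained and
#' reproducible.  Gate steady states are Boltzmann functions
#' `1/(1+exp(-(V-th)/k))` (k < 0 for inactivation written with the opposite
#' sign); time constants are either fixed or sigmoid in V.  The slow pair
#' that organizes bursting: `n` (T-type Ca2+ activation, autocatalytic,
#' tau `n_tau` ms) and `o` (Ca2+-gated KCa activation, negative feedback,
#' tau `o_tau` ms).  The M-current gate `w` uses Kv7-like midpoint and a
#' 150 ms time constant.  Ca2+ dynamics: single well-mixed pool,
#' d[Ca]/dt = -ca_k * I_Ca - ([Ca]-ca_rest)/ca_tau, [Ca] in uM.
#'
#' @param ... name = value overrides.
#' @return named numeric vector of rate constants.
#' @export
kinetics_constants <- function(...) {
  k <- c(
    vt = thermal_voltage_mV(),  # RT/F, mV
    ca_ext = 2,                 # mM external Ca2+
    # normalization of the constant-field driving term: the printed Ca2+
    # "conductance" magnitudes are permeability-like (they are tabulated in
    # different units than the K+ rows); dividing the GHK driving term by
    # ca_drive maps them onto currents of physiological size
    ca_drive = 10,
    # fast Na+: m3h; h time constant is a Gaussian bell centered near spike
    # threshold so inactivation does not equilibrate during the interspike
    # passage (the classical HH arrangement)
    m_th = -42, m_k = 5, m_tau = 0.05,
    h_th = -40, h_k = 3, h_tau0 = 0.8, h_tauA = 20, h_tth = -38, h_tk = 8,
    # delayed rectifier: nk^4
    nk_th = -45, nk_k = 4, nk_tau0 = 5, nk_tauA = 0, nk_tth = -30, nk_tk = 10,
    # A-type: a (fast act), b (inact)
    a_th = -50, a_k = 6, a_tau = 1,
    b_th = -75, b_k = 7, b_tau = 50,
    # T-type Ca2+ slow activation (slow autocatalytic variable); deactivates
    # quickly at hyperpolarized potentials, slowly when depolarized
    n_th = -50, n_k = 5, n_tau0 = 20, n_tauA = 280, n_tth = -40, n_tk = 6,
    # KCa slow activation by Ca2+ (slow negative feedback variable)
    o_kd = 3, o_hill = 3, o_tau = 120,
    # M-current gate (Kv7-like)
    w_th = -28, w_k = 10, w_tau = 200,
    # slow AHP gate
    q_kd = 5, q_hill = 4, q_tau = 1000,
    # Ca2+ pool: influx scale (uM cm^2 / uA / ms) and clearance (ms)
    ca_k = 0.025, ca_tau = 150, ca_rest = 0.05,
    # high-threshold Ca2+ activation (instantaneous, squared)
    mL_th = -20, mL_k = 5,
    mN_th = -28, mN_k = 5
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(k))
    if (length(bad)) stop("unknown kinetics constant(s): ",
                          paste(bad, collapse = ", "))
    k[names(ov)] <- unlist(ov)
  }
  k
}
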