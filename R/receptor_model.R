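#' Effective off-rate of the ligand-TCR complex under 660 nm light
#'
#' The bivalent ON-state complex dissociates either intrinsically (rate
#' `k_off`, light-independent) or because bound PhyB photoconverts to the
#' non-binding OFF state (rate `k_i = (1 - phi_eq) * k_c * I`). The effective
#' off-rate is their sum, an affine and strictly increasing function of
#' intensity.
#'
#' @param params A [model_params()] object.
#' @param intensity Intensity in percent of maximal 660 nm output, in
#'   \[0, 100\]; vectorized.
#' @return Effective off-rate(s), s^-1.
#' @export
effective_off_rate <- function(params, intensity) {
  stopifnot(inherits(params, "model_params"))
  params$binding$k_off + rate_on_to_off(params$photophys, intensity)
}

#' Half-life of the ligand-TCR complex
#'
#' `ln 2 / (k_off + k_i(I))`; strictly decreasing in intensity.
#'
#' @inheritParams effective_off_rate
#' @return Half-life (or -lives), seconds.
#' @export
complex_half_life <- function(params, intensity) {
  log(2) / effective_off_rate(params, intensity)
}

#' Effective dissociation constant under 660 nm light
#'
#' With a light-independent on-rate, `K_eff(I) = K0 * k_eff(I) / k_off`, so
#' the effective affinity `1/K_eff` is the reciprocal of an affine function
#' of intensity.
#'
#' @inheritParams effective_off_rate
#' @return Effective K_d(s), nM.
#' @export
effective_Kd <- function(params, intensity) {
  params$binding$K0 * effective_off_rate(params, intensity) /
    params$binding$k_off
}

#' Steady-state receptor occupancy
#'
#' Fraction of receptors bound by ON-state ligand at steady state, with the
#' ligand in excess: `occ = L_on / (L_on + K_eff(I))`, where
#' `L_on = f_on * ligand`. Under continuous 660 nm light `f_on` is the
#' photoequilibrium fraction `phi_eq`; the same value applies in the dark
#' with ligand pre-converted by saturating 660 nm light (the dark limit
#' `I = 0` uses `K_eff = K0`).
#'
#' @inheritParams effective_off_rate
#' @param ligand Total ligand concentration(s), nM (>= 0).
#' @param on_fraction Current ON fraction of the ligand; defaults to
#'   `phi_eq`.
#' @return Occupancy in \[0, 1).
#' @export
steady_state_occupancy <- function(params, intensity, ligand,
                                   on_fraction = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (any(ligand < 0)) stop("'ligand' must be non-negative")
  if (is.null(on_fraction)) on_fraction <- params$photophys$phi_eq
  if (any(on_fraction < 0) || any(on_fraction > 1))
    stop("'on_fraction' must lie in [0, 1]")
  L_on <- on_fraction * ligand
  L_on / (L_on + effective_Kd(params, intensity))
}

#' Kinetic-proofreading survival probability
#'
#' Probability that a complex with exponentially distributed lifetime (rate
#' `k_eff`) survives at least the KPR time: `exp(-k_eff * tau_kpr)`. Equals
#' 1 at `tau_kpr = 0` (the occupancy null) and exactly 1/2 when the complex
#' half-life `ln2 / k_eff` equals `tau_kpr` — the half-maximal-signaling
#' identity.
#'
#' @param tau_kpr KPR time, s (>= 0).
#' @param k_eff Effective off-rate(s), s^-1 (> 0).
#' @return Survival probability in (0, 1\].
#' @export
kpr_survival <- function(tau_kpr, k_eff) {
  if (any(tau_kpr < 0)) stop("'tau_kpr' must be non-negative")
  if (any(k_eff <= 0)) stop("'k_eff' must be positive")
  exp(-k_eff * tau_kpr)
}

#' Predicted steady-state calcium response under continuous 660 nm light
#'
#' `A * occupancy(I, L) * exp(-k_eff(I) * tau_kpr)`: the amplitude times the
#' fraction of receptors that are bound *and* whose complex survived the
#' proofreading time. At `tau_kpr = 0` this reduces exactly to the occupancy
#' readout. The `I -> 0` limit is the dark-trapped maximum
#' `A * occ_dark * exp(-k_off * tau_kpr)`.
#'
#' @inheritParams steady_state_occupancy
#' @return Predicted calcium response(s), a.u. (normalized scale).
#' @export
calcium_steady_state <- function(params, intensity, ligand) {
  k_eff <- effective_off_rate(params, intensity)
  params$obs$A * steady_state_occupancy(params, intensity, ligand) *
    kpr_survival(params$kpr$tau_kpr, k_eff)
}

#' Predicted calcium response after an ON-trapping 660 nm pulse
#'
#' All-OFF ligand receives a 660 nm pulse of the given intensity and
#' duration, trapping an ON-ligand concentration
#' `L_on(d) = ligand * phi_eq * (1 - exp(-k_c * I * d))`; the response is
#' then read out in the dark:
#' `A * L_on(d) / (L_on(d) + K0) * exp(-k_off * tau_kpr)`. Monotone
#' increasing and saturating in the pulse duration; the infinite-duration
#' limit equals the dark steady-state response of fully pre-converted ligand.
#'
#' @inheritParams steady_state_occupancy
#' @param duration Pulse duration(s), seconds (>= 0; vectorized).
#' @return Predicted calcium response(s), a.u.
#' @export
calcium_after_pulse <- function(params, intensity, duration, ligand) {
  stopifnot(inherits(params, "model_params"))
  if (any(ligand < 0)) stop("'ligand' must be non-negative")
  f_on <- pulse_trapped_on_fraction(params$photophys, intensity, duration)
  L_on <- ligand * f_on
  params$obs$A * L_on / (L_on + params$binding$K0) *
    exp(-params$binding$k_off * params$kpr$tau_kpr)
}

#' Predicted bound-ligand readout (MFI)
#'
#' `s_bind * occupancy(I, L) + bg_bind`; strictly decreasing in intensity at
#' fixed ligand because the effective affinity falls with intensity.
#'
#' @inheritParams steady_state_occupancy
#' @return Predicted bound signal(s), MFI.
#' @export
predicted_binding <- function(params, intensity, ligand) {
  params$obs$s_bind * steady_state_occupancy(params, intensity, ligand) +
    params$obs$bg_bind
}

#' Half-maximal-response threshold intensity
#'
#' The 660 nm intensity at which the steady-state calcium response falls to
#' half its low-intensity (dark-trapped) plateau, found by bracketed
#' root-finding on (0, 100\]; the response is monotone decreasing in
#' intensity, so the root is unique. In the proofreading regime this
#' threshold is approximately independent of the ligand concentration.
#'
#' @inheritParams steady_state_occupancy
#' @param tol Root-finding tolerance on the intensity, percent.
#' @return Threshold intensity, percent.
#' @export
threshold_intensity <- function(params, ligand, tol = 1e-8) {
  stopifnot(inherits(params, "model_params"), length(ligand) == 1, ligand > 0)
  plateau <- params$obs$A * steady_state_occupancy(params, 0, ligand) *
    exp(-params$binding$k_off * params$kpr$tau_kpr)
  g <- function(I) calcium_steady_state(params, I, ligand) - plateau / 2
  if (g(100) > 0)
    stop("no half-response threshold in (0, 100]: response at 100% is above half the plateau")
  stats::uniroot(g, interval = c(1e-9, 100), tol = tol)$root
}
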