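#' Photophysical parameters of the PhyB two-state photocycle
#'
#' PhyB shuttles between a PIF-binding ON state and a non-binding OFF state.
#' Under 660 nm light both directions are driven, so the photocycle relaxes
#' toward a fixed ON:OFF photoequilibrium (80:20) at a total cycling rate
#' `k_c * intensity`; the intensity sets only the cycling speed, not the
#' equilibrium. Under 740 nm light the ON state is emptied at rate `k_740`,
#' and in darkness both states are frozen on experimental timescales.
#'
#' @param k_c Total 660 nm photocycling rate constant, s^-1 per percent
#'   intensity. At intensity `I` the OFF->ON rate is `phi_eq * k_c * I` and
#'   the ON->OFF rate is `(1 - phi_eq) * k_c * I`.
#' @param phi_eq ON fraction at 660 nm photoequilibrium (dimensionless,
#'   default 0.8). Fixed, not fitted.
#' @param k_740 ON->OFF rate under 740 nm light, s^-1. Large by default so a
#'   1 s full-intensity pulse empties the ON state; not fitted.
#'
#' @return An object of class `photophys_params`.
#' @examples
#' pp <- photophys_params(k_c = 0.05)
#' rate_on_to_off(pp, 100)
#' @export
photophys_params <- function(k_c, phi_eq = 0.8, k_740 = 2) {
  stopifnot(is.numeric(k_c), length(k_c) == 1, is.finite(k_c))
  if (k_c <= 0) stop("'k_c' must be positive")
  if (!(phi_eq > 0 && phi_eq < 1)) stop("'phi_eq' must lie strictly in (0, 1)")
  if (k_740 <= 0) stop("'k_740' must be positive")
  structure(list(k_c = k_c, phi_eq = phi_eq, k_740 = k_740),
            class = "photophys_params")
}

#' Binding parameters of the bivalent PhyBt-TCR complex
#'
#' The tetrameric ligand bound bivalently to the receptor is treated as a
#' single complex with one light-independent off-rate `k_off` and a dark-state
#' effective dissociation constant `K0 = k_off / k_on`; the on-rate is derived
#' and light-independent, so light enters only through the effective off-rate.
#'
#' @param k_off Light-independent off-rate of the complex, s^-1.
#' @param K0 Dark-state effective dissociation constant of ON-state ligand for
#'   the receptor, nM.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(k_off, K0) {
  if (!is.numeric(k_off) || length(k_off) != 1 || !is.finite(k_off) || k_off <= 0)
    stop("'k_off' must be a positive number")
  if (!is.numeric(K0) || length(K0) != 1 || !is.finite(K0) || K0 <= 0)
    stop("'K0' must be a positive number")
  structure(list(k_off = k_off, K0 = K0), class = "binding_params")
}

#' Kinetic-proofreading parameters
#'
#' @param tau_kpr KPR time in seconds: the duration the bivalent complex must
#'   survive for the receptor-proximal signaling steps to complete.
#'   `tau_kpr = 0` recovers the occupancy (no-proofreading) null model.
#' @return An object of class `kpr_params`.
#' @export
kpr_params <- function(tau_kpr) {
  if (!is.numeric(tau_kpr) || length(tau_kpr) != 1 || !is.finite(tau_kpr) ||
      tau_kpr < 0)
    stop("'tau_kpr' must be a non-negative number")
  structure(list(tau_kpr = tau_kpr), class = "kpr_params")
}

#' Observation-layer parameters
#'
#' Maps the dimensionless model outputs onto the measured scales: calcium is
#' reported in arbitrary units normalized so the internal 20 nM dark-ON
#' control defines 1, and bound ligand is reported as fluorescence (MFI)
#' proportional to occupancy.
#'
#' @param A Calcium response amplitude on the normalized a.u. scale.
#' @param s_bind Binding readout scale, MFI per occupancy unit. Profiled out
#'   analytically during fitting; kept here for forward simulation.
#' @param bg_bind Binding background, MFI (default 0: unspecific binding is
#'   assumed subtracted upstream).
#' @return An object of class `observation_params`.
#' @export
observation_params <- function(A, s_bind = 1, bg_bind = 0) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0)
    stop("'A' must be a positive number")
  if (s_bind <= 0) stop("'s_bind' must be positive")
  if (bg_bind < 0) stop("'bg_bind' must be non-negative")
  structure(list(A = A, s_bind = s_bind, bg_bind = bg_bind),
            class = "observation_params")
}

#' Full model parameter set
#'
#' Bundles the five free structural parameters of the photoswitching-binding-
#' proofreading model — `k_c`, `k_off`, `K0`, `tau_kpr`, `A` — together with
#' the fixed photoequilibrium fraction and 740 nm rate, and the observation
#' scales for the binding readout.
#'
#' @inheritParams photophys_params
#' @inheritParams binding_params
#' @inheritParams kpr_params
#' @inheritParams observation_params
#' @return An object of class `model_params` with components `photophys`,
#'   `binding`, `kpr` and `obs`.
#' @examples
#' p <- model_params(k_c = 0.017, k_off = 0.011, K0 = 500, tau_kpr = 8, A = 35)
#' calcium_steady_state(p, intensity = c(0, 2, 100), ligand = 20)
#' @export
model_params <- function(k_c, k_off, K0, tau_kpr, A, phi_eq = 0.8, k_740 = 2,
                         s_bind = 1, bg_bind = 0) {
  structure(list(
    photophys = photophys_params(k_c, phi_eq = phi_eq, k_740 = k_740),
    binding = binding_params(k_off, K0),
    kpr = kpr_params(tau_kpr),
    obs = observation_params(A, s_bind = s_bind, bg_bind = bg_bind)
  ), class = "model_params")
}

#' Default ground-truth parameters in the fitted regime of the system
#'
#' Constructs a parameter set anchored to the quantitative regime reported
#' for the opto-ligand-TCR system: complex half-life ln2/(k_off + k_i)
#' spanning 40 s at the lowest continuous intensity (2%) down to 2 s at 100%,
#' KPR time 8 s, weak binding (K0 well above the working ligand
#' concentrations, which makes the threshold intensity approximately
#' concentration-independent), and amplitude `A` normalized so the 20 nM
#' dark-ON internal control predicts exactly 1 a.u.
#'
#' `k_c` and `k_off` are solved from the two half-life anchors:
#' `k_off + (1 - phi_eq) * k_c * I` equals `ln2 / 40` at `I = 2` and
#' `ln2 / 2` at `I = 100`.
#'
#' @param half_life_low,intensity_low Complex half-life (s) at the lowest
#'   intensity (percent) used in the steady-state design.
#' @param half_life_high,intensity_high Complex half-life (s) at full
#'   intensity.
#' @param K0 Dark-state dissociation constant, nM.
#' @param tau_kpr KPR time, s.
#' @param phi_eq Photoequilibrium ON fraction.
#' @param control_ligand Ligand concentration (nM) of the dark internal
#'   control that defines 1 a.u.
#' @return A `model_params` object.
#' @examples
#' p <- default_model_params()
#' complex_half_life(p, c(2, 100))
#' @export
default_model_params <- function(half_life_low = 40, intensity_low = 2,
                                 half_life_high = 2, intensity_high = 100,
                                 K0 = 500, tau_kpr = 8, phi_eq = 0.8,
                                 control_ligand = 20) {
  k_low <- log(2) / half_life_low
  k_high <- log(2) / half_life_high
  k_c <- (k_high - k_low) / ((1 - phi_eq) * (intensity_high - intensity_low))
  k_off <- k_low - (1 - phi_eq) * k_c * intensity_low
  if (k_off <= 0)
    stop("half-life anchors imply a non-positive 'k_off'")
  occ_dark <- phi_eq * control_ligand / (phi_eq * control_ligand + K0)
  A <- 1 / (occ_dark * exp(-k_off * tau_kpr))
  model_params(k_c = k_c, k_off = k_off, K0 = K0, tau_kpr = tau_kpr, A = A,
               phi_eq = phi_eq)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Opto-ligand-TCR model parameters\n")
  cat(sprintf("  k_c     %.5g s^-1 %%^-1  (photocycling rate constant)\n",
              x$photophys$k_c))
  cat(sprintf("  phi_eq  %.3g             (photoequilibrium ON fraction, fixed)\n",
              x$photophys$phi_eq))
  cat(sprintf("  k_off   %.5g s^-1       (light-independent off-rate)\n",
              x$binding$k_off))
  cat(sprintf("  K0      %.5g nM         (dark-state dissociation constant)\n",
              x$binding$K0))
  cat(sprintf("  tau_kpr %.5g s          (KPR time)\n", x$kpr$tau_kpr))
  cat(sprintf("  A       %.5g a.u.       (calcium amplitude)\n", x$obs$A))
  invisible(x)
}

# Named vector of the five free structural parameters.
#' Extract the five free structural parameters as a named vector
#' @param params A `model_params` object.
#' @return Named numeric vector `c(k_c, k_off, K0, tau_kpr, A)`.
#' @export
structural_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(k_c = params$photophys$k_c, k_off = params$binding$k_off,
    K0 = params$binding$K0, tau_kpr = params$kpr$tau_kpr, A = params$obs$A)
}
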