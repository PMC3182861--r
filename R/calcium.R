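# Intracellular calcium dynamics: a per-compartment leaky-integrator pool
# driven by the calcium currents (Ca_T + Ca_L) and relaxing to a basal
# concentration. This pool gates I_AHP and I_CAN.

#' Calcium pool parameters
#'
#' Leaky-integrator model of the submembrane calcium concentration:
#' `d[Ca]/dt = -alpha * I_Ca - ([Ca] - Ca_rest) / tau_Ca`,
#' with inward (negative) calcium current raising the concentration.
#' `alpha` converts a calcium current density into a concentration rate in
#' the thin shell just inside the membrane; with I_Ca in mA/cm^2, time in ms
#' and concentrations in mM its working value is alpha (mM/ms per mA/cm^2).
#'
#' @param alpha current-to-concentration conversion factor, 0.0155
#' @param tau_Ca decay time constant, ms
#' @param Ca_rest basal concentration, mM (50 nM)
#' @return list of class `calcium_params`
#' @export
calcium_params <- function(alpha = 0.0155, tau_Ca = 50, Ca_rest = 5e-5) {
  stopifnot(alpha > 0, tau_Ca > 0, Ca_rest > 0)
  p <- list(alpha = alpha, tau_Ca = tau_Ca, Ca_rest = Ca_rest)
  class(p) <- "calcium_params"
  p
}

#' Advance the calcium pool by one time step
#'
#' Unconditionally stable exact-exponential update of the leaky integrator
#' (the same scheme the cable solver uses), clamped at zero from below: for
#' the current held constant over the step the update is the analytic
#' solution, relaxing towards the fixed point
#' `Ca_ss = Ca_rest - alpha * tau_Ca * I_Ca`.
#'
#' @param ca_i current concentration, mM (vectorized over compartments)
#' @param i_ca calcium current density (Ca_T + Ca_L), mA/cm^2; negative =
#'   inward
#' @param dt time step, ms
#' @param p a [calcium_params()]
#' @return updated concentration, mM
#' @export
step_calcium <- function(ca_i, i_ca, dt, p = calcium_params()) {
  stopifnot(dt > 0, all(ca_i >= 0))
  ss <- p$Ca_rest - p$alpha * p$tau_Ca * i_ca
  out <- ss + (ca_i - ss) * exp(-dt / p$tau_Ca)
  pmax(out, 0)
}

#' Steady-state calcium concentration under constant current
#' @param i_ca constant calcium current density, mA/cm^2
#' @param p a [calcium_params()]
#' @return fixed point of the leaky integrator, mM (floored at 0)
#' @export
calcium_steady_state <- function(i_ca, p = calcium_params()) {
  pmax(p$Ca_rest - p$alpha * p$tau_Ca * i_ca, 0)
}
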