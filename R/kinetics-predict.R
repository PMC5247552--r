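#' Target-size photoinactivation decay
#'
#' Active PSII content under illumination with repair blocked declines as a
#' single exponential in cumulative photon dose,
#' `A(t) = a0 * exp(-sigma_i * E * t)` where `E` is the photon flux
#' corresponding to irradiance `I`. The equivalent first-order rate constant
#' is `k_pi = sigma_i * E`.
#'
#' @param a0 Active PSII at treatment onset (any consistent content unit).
#' @param sigma_i Target size, m^2 photon^-1.
#' @param irradiance Irradiance, umol photons m^-2 s^-1.
#' @param t Time since treatment onset, s. Vectorised.
#' @return Predicted active PSII content at `t`.
#' @examples
#' predict_active_decay(42, 3.6e-24, 97, 1800)
#' @export
predict_active_decay <- function(a0, sigma_i, irradiance, t) {
  if (a0 <= 0) stop_invalid("`a0` must be > 0.")
  if (sigma_i < 0) stop_invalid("`sigma_i` must be >= 0.")
  a0 * exp(-sigma_i * photon_flux(irradiance) * t)
}

#' Two-state damage-repair (Kok) recovery model
#'
#' Closed-form solution of `dA/dt = -k_pi * A + k_rec * (a0 - A)`, the
#' two-state model in which all PSII starts active and inactivated centres
#' are the only repair substrate:
#' `A(t) = a0 * (k_rec + k_pi * exp(-(k_pi + k_rec) * t)) / (k_pi + k_rec)`.
#'
#' @param a0 Active PSII at treatment onset.
#' @param k_pi First-order photoinactivation rate constant, s^-1.
#' @param k_rec First-order repair rate constant, s^-1.
#' @param t Time since treatment onset, s. Vectorised.
#' @return Predicted active PSII content.
#' @export
predict_kok_recovery <- function(a0, k_pi, k_rec, t) {
  if (a0 <= 0) stop_invalid("`a0` must be > 0.")
  if (k_pi < 0 || k_rec < 0) stop_invalid("Rates must be >= 0.")
  ktot <- k_pi + k_rec
  if (ktot == 0) {
    return(rep(a0, length(t)))
  }
  a0 * (k_rec + k_pi * exp(-ktot * t)) / ktot
}

#' Damage-repair model allowing an initial inactive pool
#'
#' Closed-form solution of `dA/dt = -k_pi * A + k_recinact * (T - A)` with
#' total pool `T = a0 + i0`: cells may carry a pre-existing pool of
#' photoinactivated-but-intact PSII at treatment onset, which is already a
#' substrate for repair. With `r = k_recinact / (k_pi + k_recinact)`,
#' `A(t) = T*r + (a0 - T*r) * exp(-(k_pi + k_recinact) * t)`. With `i0 = 0`
#' this reduces exactly to [predict_kok_recovery()]. Ignoring a genuine
#' initial inactive pool inflates fitted repair rate constants under the
#' simple two-state model.
#'
#' @param a0 Active PSII at treatment onset.
#' @param i0 Inactive PSII at treatment onset (same unit).
#' @param k_pi Photoinactivation rate constant, s^-1.
#' @param k_recinact Repair rate constant, s^-1.
#' @param t Time since treatment onset, s. Vectorised.
#' @return Predicted active PSII content.
#' @examples
#' predict_recovery_with_inactive_pool(42, 37, 2.103e-4, 7e-5, 1800)
#' @export
predict_recovery_with_inactive_pool <- function(a0, i0, k_pi, k_recinact, t) {
  if (a0 <= 0) stop_invalid("`a0` must be > 0.")
  if (i0 < 0) stop_invalid("`i0` must be >= 0.")
  if (k_pi < 0 || k_recinact < 0) stop_invalid("Rates must be >= 0.")
  ktot <- k_pi + k_recinact
  if (ktot == 0) {
    return(rep(a0, length(t)))
  }
  total <- a0 + i0
  asym <- total * k_recinact / ktot
  asym + (a0 - asym) * exp(-ktot * t)
}

#' Photochemical quenching light-saturation law
#'
#' Michaelis-Menten style decline of the open-PSII fraction with light:
#' `qP(I) = ke_qp / (ke_qp + I)`, i.e. `1 - I / (ke_qp + I)`. `ke_qp` is the
#' irradiance at which half the centres are closed.
#'
#' @param irradiance Irradiance, umol photons m^-2 s^-1. Vectorised.
#' @param ke_qp Half-saturation light level, umol photons m^-2 s^-1.
#' @return Predicted qP in (0, 1].
#' @export
predict_qp <- function(irradiance, ke_qp) {
  if (ke_qp <= 0) stop_invalid("`ke_qp` must be > 0.")
  if (any(irradiance < 0)) stop_invalid("`irradiance` must be >= 0.")
  ke_qp / (ke_qp + irradiance)
}

#' NPQ induction model: fast saturating phase plus slow cumulative phase
#'
#' Y(NPQ) under constant irradiance rises as a first-order approach to a
#' light-saturating amplitude, plus a zero-order phase that accumulates
#' linearly with cumulative illuminated time:
#' `Y(NPQ)(t) = S * (1 - exp(-k_npq * t)) + k_npqslow * t_cum`, with
#' amplitude `S = I / (ke_npq + I)`. The result is clipped to `[0, 1)`
#' since Y(NPQ) is a quantum yield.
#'
#' @param irradiance Irradiance, umol photons m^-2 s^-1.
#' @param t Time since onset of the current light level, s. Vectorised.
#' @param t_cum Cumulative illuminated time, s (recycled against `t`).
#' @param ke_npq Half-saturation light level, umol photons m^-2 s^-1.
#' @param k_npq First-order induction rate constant, s^-1.
#' @param k_npqslow Zero-order slow-phase rate constant, s^-1.
#' @return Predicted Y(NPQ) in `[0, 1)`.
#' @examples
#' predict_ynpq(97, 300, 300, ke_npq = 49, k_npq = 0.003, k_npqslow = 2e-6)
#' @export
predict_ynpq <- function(irradiance, t, t_cum, ke_npq, k_npq, k_npqslow) {
  if (ke_npq <= 0) stop_invalid("`ke_npq` must be > 0.")
  if (k_npq < 0 || k_npqslow < 0) stop_invalid("Rates must be >= 0.")
  s <- irradiance / (ke_npq + irradiance)
  y <- s * (1 - exp(-k_npq * t)) + k_npqslow * t_cum
  pmin(pmax(y, 0), 1 - 1e-12)
}

#' First-order NPQ relaxation
#'
#' Y(NPQ) relaxation after a drop to darkness or low light:
#' `Y(t) = y_end * exp(-kr_npq * t)` with `t` the time since the drop.
#'
#' @param y_end Y(NPQ) at the end of the high-light phase.
#' @param kr_npq First-order relaxation rate constant, s^-1.
#' @param t Time since onset of relaxation, s. Vectorised.
#' @return Predicted Y(NPQ).
#' @export
predict_ynpq_relaxation <- function(y_end, kr_npq, t) {
  if (y_end < 0) stop_invalid("`y_end` must be >= 0.")
  if (kr_npq < 0) stop_invalid("`kr_npq` must be >= 0.")
  y_end * exp(-kr_npq * t)
}
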