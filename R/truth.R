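#' Ground-truth kinetic parameter set for forward simulation
#'
#' Bundles every kinetic, fluorometric and pool parameter needed to simulate
#' an FRR photophysiology experiment, and serves as the known truth in
#' parameter-recovery studies. The defaults describe a cold-adapted
#' (psychrophilic) picophytoplankter growing at 2 degC under low light: a
#' large photoinactivation target size, slow repair limited by PsbA protein
#' clearance, a substantial pre-existing pool of photoinactivated-but-intact
#' PSII, strong low-light-saturating NPQ, and long electron-transport
#' lifetimes.
#'
#' @param sigma_i Target size for photoinactivation, m^2 photon^-1.
#' @param k_rec First-order PSII repair rate constant under the two-state
#'   damage-repair (Kok) model, s^-1.
#' @param k_recinact Repair rate constant under the inactive-pool variant of
#'   the damage-repair model, s^-1.
#' @param ke_qp Half-saturation light level for photochemical quenching qP,
#'   umol photons m^-2 s^-1.
#' @param ke_npq Half-saturation light level for Y(NPQ) induction,
#'   umol photons m^-2 s^-1.
#' @param k_npq First-order rate constant for NPQ induction, s^-1.
#' @param k_npqslow Zero-order rate constant for the slow, cumulative-time
#'   phase of NPQ induction, s^-1.
#' @param kr_npq First-order rate constant for NPQ relaxation in darkness or
#'   low light, s^-1.
#' @param k_psba First-order rate constant for clearance of PsbA protein,
#'   s^-1.
#' @param active_t0,inactive_t0 Active and inactive PSII pools at the start
#'   of the treatment, fmol (ug total protein)^-1.
#' @param f0,fm Dark-acclimated minimal and maximal fluorescence, relative
#'   units; `fm > f0 > 0`.
#' @param sigma_psii Effective absorbance cross section serving PSII
#'   photochemistry, A^2 quanta^-1.
#' @param rho Excitation connectivity among PSII centres, dimensionless in
#'   `[0, 1)`.
#' @param tau1,tau2 Slow and fast lifetimes for PSII reopening after a
#'   saturating flashlet train, s; `tau1 >= tau2 > 0`.
#' @param reopen_fast_frac Amplitude fraction of the fast (tau2) reopening
#'   phase, in `[0, 1]`.
#' @param npq_relax_2s Fraction of the instantaneous NPQ quench that relaxes
#'   during the 2-s dark period between the under-light and after-dark FRR
#'   inductions, in `[0, 1)`.
#' @param f0_rise Proportionality constant by which accumulated inactive
#'   PSII raises the apparent minimal fluorescence F0' (photoinactivated
#'   centres fluoresce but contribute no variable fluorescence).
#'
#' @return An object of class `kinetic_ground_truth` (a validated named
#'   list).
#' @examples
#' truth <- kinetic_ground_truth()
#' truth$sigma_i
#' @export
kinetic_ground_truth <- function(sigma_i = 3.6e-24,
                                 k_rec = 2.7e-4,
                                 k_recinact = 7e-5,
                                 ke_qp = 64,
                                 ke_npq = 49,
                                 k_npq = 0.003,
                                 k_npqslow = 2e-6,
                                 kr_npq = 3e-4,
                                 k_psba = 7e-5,
                                 active_t0 = 42,
                                 inactive_t0 = 37,
                                 f0 = 0.41,
                                 fm = 1,
                                 sigma_psii = 747,
                                 rho = 0.3,
                                 tau1 = 8.4e-3,
                                 tau2 = 5.8e-4,
                                 reopen_fast_frac = 0.5,
                                 npq_relax_2s = 0.3,
                                 f0_rise = 0.5) {
  truth <- list(
    sigma_i = sigma_i, k_rec = k_rec, k_recinact = k_recinact,
    ke_qp = ke_qp, ke_npq = ke_npq, k_npq = k_npq,
    k_npqslow = k_npqslow, kr_npq = kr_npq, k_psba = k_psba,
    active_t0 = active_t0, inactive_t0 = inactive_t0,
    f0 = f0, fm = fm, sigma_psii = sigma_psii, rho = rho,
    tau1 = tau1, tau2 = tau2, reopen_fast_frac = reopen_fast_frac,
    npq_relax_2s = npq_relax_2s, f0_rise = f0_rise
  )
  rates <- c("sigma_i", "k_rec", "k_recinact", "k_npq", "k_npqslow",
             "kr_npq", "k_psba")
  if (any(unlist(truth[rates]) < 0)) {
    stop_invalid("All rate constants and the target size must be >= 0.")
  }
  if (ke_qp <= 0 || ke_npq <= 0) {
    stop_invalid("Half-saturation constants `ke_qp` and `ke_npq` must be > 0.")
  }
  if (rho < 0 || rho >= 1) stop_invalid("`rho` must lie in [0, 1).")
  if (!(tau1 >= tau2 && tau2 > 0)) {
    stop_invalid("Reopening lifetimes must satisfy tau1 >= tau2 > 0.")
  }
  if (!(fm > f0 && f0 > 0)) stop_invalid("Fluorescence must satisfy fm > f0 > 0.")
  if (active_t0 <= 0 || inactive_t0 < 0) {
    stop_invalid("Pools must satisfy active_t0 > 0 and inactive_t0 >= 0.")
  }
  if (sigma_psii <= 0) stop_invalid("`sigma_psii` must be > 0.")
  if (reopen_fast_frac < 0 || reopen_fast_frac > 1) {
    stop_invalid("`reopen_fast_frac` must lie in [0, 1].")
  }
  if (npq_relax_2s < 0 || npq_relax_2s >= 1) {
    stop_invalid("`npq_relax_2s` must lie in [0, 1).")
  }
  if (f0_rise < 0) stop_invalid("`f0_rise` must be >= 0.")
  structure(truth, class = "kinetic_ground_truth")
}

#' @export
print.kinetic_ground_truth <- function(x, ...) {
  cat("<kinetic_ground_truth>\n")
  vals <- vapply(x, format, character(1), digits = 4)
  cat(paste0("  ", format(names(vals)), " = ", vals), sep = "\n")
  invisible(x)
}

#' Light program for a treatment time course
#'
#' Describes the sequence of illumination phases applied to a culture
#' sample. The standard protocol is 300 s darkness, 300 s at the growth
#' light, several consecutive 300-s periods at the treatment light, then a
#' 300-s recovery period at low light, with an FRR measurement at the end of
#' every interval.
#'
#' @param phase Character vector of phase labels, each one of `"dark"`,
#'   `"growth"`, `"treatment"`, `"recovery"`.
#' @param irradiance Irradiance of each phase, umol photons m^-2 s^-1.
#' @param duration Duration of each phase, s.
#' @param interval_s Measurement interval within phases, s (default 300).
#'
#' @return A tibble of class `light_program` with columns `phase`,
#'   `irradiance`, `duration`, and attribute `interval_s`.
#' @seealso [standard_light_program()]
#' @export
light_program <- function(phase, irradiance, duration, interval_s = 300) {
  ok <- c("dark", "growth", "treatment", "recovery")
  if (!all(phase %in% ok)) {
    stop_invalid(paste0("Phase labels must be one of: ",
                        paste(ok, collapse = ", "), "."))
  }
  if (any(duration <= 0)) stop_invalid("Phase durations must be > 0.")
  if (any(irradiance < 0)) stop_invalid("Irradiance must be >= 0.")
  if (interval_s <= 0) stop_invalid("`interval_s` must be > 0.")
  out <- tibble(phase = phase, irradiance = as.numeric(irradiance),
                duration = as.numeric(duration))
  attr(out, "interval_s") <- interval_s
  class(out) <- c("light_program", class(out))
  out
}

#' Standard dark / growth / treatment / recovery program
#'
#' Convenience constructor for the usual protocol: 300 s dark, 300 s growth
#' light, `n_treatment` consecutive 300-s treatment periods, and 300 s of
#' low recovery light.
#'
#' @param treatment Treatment irradiance, umol photons m^-2 s^-1.
#' @param growth Growth irradiance (default 36).
#' @param recovery Recovery irradiance (default 12).
#' @param n_treatment Number of 300-s treatment periods (default 6).
#' @param n_recovery Number of 300-s recovery periods (default 1).
#' @param interval_s Interval length, s (default 300).
#' @return A `light_program`.
#' @export
standard_light_program <- function(treatment, growth = 36, recovery = 12,
                                   n_treatment = 6, n_recovery = 1,
                                   interval_s = 300) {
  light_program(
    phase = c("dark", "growth", "treatment", "recovery"),
    irradiance = c(0, growth, treatment, recovery),
    duration = c(interval_s, interval_s,
                 n_treatment * interval_s, n_recovery * interval_s),
    interval_s = interval_s
  )
}

#' Observation-noise specification
#'
#' Controls the stochastic layer applied on top of every noiseless forward
#' simulation. Identical seeds give bit-identical simulated data; no global
#' random state is consulted or modified.
#'
#' @param multiplicative_cv Coefficient of variation of multiplicative
#'   Gaussian noise applied to fluorescence-type quantities (default 0.02).
#' @param additive_sd Standard deviation of additive Gaussian noise, in the
#'   units of the simulated quantity (default 0).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(0.02, seed = 1)
#' noise_free() # exact forward model
#' @export
noise_spec <- function(multiplicative_cv = 0.02, additive_sd = 0, seed = 1L) {
  if (multiplicative_cv < 0 || additive_sd < 0) {
    stop_invalid("Noise magnitudes must be >= 0.")
  }
  structure(
    list(multiplicative_cv = multiplicative_cv,
         additive_sd = additive_sd,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' @rdname noise_spec
#' @export
noise_free <- function() noise_spec(0, 0, seed = 0L)

# Vector of multiplicative error factors (1 + eps), one per observation,
# drawn under the noise spec's seed. `salt` decorrelates distinct error
# sources simulated under one seed.
noise_factors <- function(noise, n, salt = 0L) {
  if (noise$multiplicative_cv == 0) {
    return(rep(1, n))
  }
  withr::with_seed(noise$seed + as.integer(salt), {
    1 + rnorm(n, 0, noise$multiplicative_cv)
  })
}

# Apply a noise_spec to a numeric vector under the spec's own seed, leaving
# the caller's RNG state untouched. `salt` decorrelates multiple quantities
# simulated under one seed.
apply_noise <- function(x, noise, salt = 0L) {
  if (noise$multiplicative_cv == 0 && noise$additive_sd == 0) {
    return(x)
  }
  withr::with_seed(noise$seed + as.integer(salt), {
    x * (1 + rnorm(length(x), 0, noise$multiplicative_cv)) +
      rnorm(length(x), 0, noise$additive_sd)
  })
}
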