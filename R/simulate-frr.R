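# Cumulative-closure model for a flashlet induction train.
#
# Per-flashlet update of the closed fraction C with excitation connectivity
# rho (energy transfer from closed to open neighbours):
#   C <- C + E * sigma * (1 - C) * (1 - rho) / (1 - rho * C)
# and observed fluorescence
#   F = F0 + (FM - F0) * C * (1 - rho) / (1 - rho * C).
# Reopening during the ~128-us train is negligible and ignored.
# `excitation` is the per-flashlet dose in quanta A^-2; `sigma` in A^2
# quanta^-1, so the product is a dimensionless closure increment.
frr_closure_curve <- function(excitation, f0, fm, sigma, rho) {
  n <- length(excitation)
  closed <- numeric(n)
  c_now <- 0
  for (k in seq_len(n)) {
    c_now <- c_now +
      excitation[k] * sigma * (1 - c_now) * (1 - rho) / (1 - rho * c_now)
    c_now <- min(c_now, 1)
    closed[k] <- c_now
  }
  f0 + (fm - f0) * closed * (1 - rho) / (1 - rho * closed)
}

#' Simulate an FRR flashlet induction trace
#'
#' Forward-simulates the fluorescence response to a train of sub-saturating
#' flashlets (default 40 flashlets of 1.2 us separated by 2 us darkness)
#' that cumulatively close PSII, followed by a reopening tail in which the
#' flash rate slows and fluorescence relaxes back towards F0 as a two-phase
#' exponential with lifetimes `tau1` (slow) and `tau2` (fast).
#'
#' @param truth A [kinetic_ground_truth()] supplying `f0`, `fm`,
#'   `sigma_psii`, `rho`, `tau1`, `tau2` and `reopen_fast_frac`.
#' @param flashlet_count Number of induction flashlets (>= 10; default 40).
#' @param flashlet_energy Excitation dose per flashlet, quanta A^-2. Zero is
#'   permitted only as a degenerate test case (flat trace at f0); negative
#'   values are an error.
#' @param noise A [noise_spec()]; multiplicative noise is applied to the
#'   fluorescence samples.
#' @param reopening_span Duration of the reopening tail, s (default 0.25).
#' @param reopening_points Samples in the reopening tail (default 60).
#' @param context Context tag recorded on the trace: `"dark-acclimated"`,
#'   `"under-light"` or `"after-2s-dark"`.
#' @return A tibble of class `frr_trace` with columns `time_s`,
#'   `excitation_quanta_per_A2`, `fluorescence`, `phase`
#'   (`"induction"`/`"reopening"`) and `context`.
#' @examples
#' tr <- simulate_frr_trace(kinetic_ground_truth(), noise = noise_free())
#' @export
simulate_frr_trace <- function(truth,
                               flashlet_count = 40,
                               flashlet_energy = 1.5e-4,
                               noise = noise_spec(),
                               reopening_span = 0.25,
                               reopening_points = 60,
                               context = "dark-acclimated") {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  if (flashlet_count < 10) stop_invalid("`flashlet_count` must be >= 10.")
  if (flashlet_energy < 0) stop_invalid("`flashlet_energy` must be >= 0.")

  # 1.2-us flashlet + 2-us dark gap
  dt <- 1.2e-6 + 2e-6
  t_ind <- (seq_len(flashlet_count) - 1) * dt
  e <- rep(flashlet_energy, flashlet_count)
  f_ind <- frr_closure_curve(e, truth$f0, truth$fm, truth$sigma_psii,
                             truth$rho)

  t_end <- t_ind[flashlet_count] + dt
  # log-spaced tail: reopening spans sub-ms (tau2) to ~10-ms (tau1)
  # lifetimes, so sampling must be dense immediately after the train
  t_re <- t_end + c(0, exp(seq(log(5e-5), log(reopening_span),
                               length.out = reopening_points - 1)))
  f_sat <- f_ind[flashlet_count]
  amp <- f_sat - truth$f0
  rel <- t_re - t_end
  decay <- truth$reopen_fast_frac * exp(-rel / truth$tau2) +
    (1 - truth$reopen_fast_frac) * exp(-rel / truth$tau1)
  f_re <- truth$f0 + amp * decay

  out <- tibble(
    time_s = c(t_ind, t_re),
    excitation_quanta_per_A2 = c(e, rep(0, reopening_points)),
    fluorescence = apply_noise(c(f_ind, f_re), noise),
    phase = rep(c("induction", "reopening"),
                c(flashlet_count, reopening_points)),
    context = context
  )
  class(out) <- c("frr_trace", class(out))
  out
}
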