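# Latent per-interval state for a light program: active pool, Y(NPQ), qP.
#
# Conventions (documented in the methods vignette):
# * the pre-treatment dark and growth phases represent the growth-acclimated
#   steady state: pools stay at (active_t0, inactive_t0) and Y(NPQ) = 0;
# * pool dynamics and NPQ induction start at treatment onset, with t
#   measured from that onset and t_cum the cumulative treatment time;
# * during the recovery phase the pools keep evolving under the recovery
#   light while Y(NPQ) relaxes first-order from its end-of-treatment value;
# * qP responds instantaneously to the current irradiance.
latent_time_course <- function(truth, program, inhibitor) {
  interval_s <- attr(program, "interval_s")
  if (is.null(interval_s)) interval_s <- 300

  k_rep <- if (inhibitor == "lincomycin") 0 else truth$k_recinact
  k_slow <- if (inhibitor == "DTT") 0 else truth$k_npqslow
  total <- truth$active_t0 + truth$inactive_t0

  rows <- list()
  t_abs <- 0          # absolute time since program start
  t_treat <- 0        # time since treatment onset
  t_cum <- 0          # cumulative treatment (illuminated) time
  a_now <- truth$active_t0
  in_dynamics <- FALSE
  y_end <- 0          # Y(NPQ) at end of last treatment phase
  t_since_recovery <- 0
  idx <- 0

  for (p in seq_len(nrow(program))) {
    phase <- program$phase[p]
    irr <- program$irradiance[p]
    dur <- program$duration[p]
    n_int <- max(1L, round(dur / interval_s))
    for (j in seq_len(n_int)) {
      step <- dur / n_int
      t_abs <- t_abs + step
      idx <- idx + 1

      if (phase == "treatment") {
        if (!in_dynamics) {
          in_dynamics <- TRUE
        }
        k_pi <- truth$sigma_i * photon_flux(irr)
        a_now <- step_pools(a_now, total, k_pi, k_rep, step)
        t_treat <- t_treat + step
        t_cum <- t_cum + step
        y_npq <- predict_ynpq(irr, t_treat, t_cum,
                              truth$ke_npq, truth$k_npq, k_slow)
        y_end <- y_npq
        t_since_recovery <- 0
      } else if (in_dynamics) {
        # recovery (or any post-treatment phase): pools evolve under the
        # current light; Y(NPQ) relaxes from its end-of-treatment value
        k_pi <- truth$sigma_i * photon_flux(irr)
        a_now <- step_pools(a_now, total, k_pi, k_rep, step)
        t_since_recovery <- t_since_recovery + step
        y_npq <- predict_ynpq_relaxation(y_end, truth$kr_npq,
                                         t_since_recovery)
      } else {
        y_npq <- 0
      }

      rows[[idx]] <- tibble(
        interval_index = idx - 1L,
        phase = phase,
        t_s = t_abs,
        t_treat_s = if (phase == "treatment") t_treat else NA_real_,
        t_cum_s = t_cum,
        t_recovery_s = if (phase == "treatment" || !in_dynamics) {
          NA_real_
        } else {
          t_since_recovery
        },
        irradiance_umol = irr,
        psii_active_true = a_now,
        psii_inactive_true = total - a_now,
        y_npq_true = y_npq,
        qp_true = predict_qp(irr, truth$ke_qp)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# One closed-form pool update over `dt` seconds with current-phase rates.
step_pools <- function(a_start, total, k_pi, k_rep, dt) {
  ktot <- k_pi + k_rep
  if (ktot == 0) {
    return(a_start)
  }
  asym <- total * k_rep / ktot
  asym + (a_start - asym) * exp(-ktot * dt)
}

# Per-active-centre F0' under quench ratio u: the Oxborough level (antenna
# quenching only) raised by the photoinactivation term, capped at 95 % of
# FM' -- under extreme combined quenching and photoinactivation F0'
# approaches FM' and qP collapses, but the levels must stay ordered.
f0_prime_per_active <- function(u, f0, fm, rise_term) {
  k_u <- 1 / (1 / f0 - 1 / fm + u / fm)        # Oxborough F0' at ratio u
  pmin(k_u * (1 + rise_term), 0.95 * fm / u)
}

# Solve for the FM quench ratio u = FM_row / FM' >= 1 such that the Table-2
# style definition Y(NPQ) = FS/FM' - FS/FM reproduces the latent y_npq,
# given qP-positioned FS and the photoinactivation-raised F0'.
# All levels scale with the active fraction, so the solve is scale-free.
solve_quench_ratio <- function(y_npq, qp, f0, fm, rise_term) {
  if (y_npq <= 0) {
    return(1)
  }
  g <- function(u) {
    f0p <- f0_prime_per_active(u, f0, fm, rise_term)
    fs <- fm / u - qp * (fm / u - f0p)
    fs * (u - 1) / fm - y_npq
  }
  upper <- 2
  while (g(upper) < 0 && upper < 1e6) upper <- upper * 2
  uniroot(g, c(1, upper), tol = 1e-12)$root
}

#' Simulate a multi-light treatment time course
#'
#' Forward-simulates per-interval FRR yield sets over a [light_program()]:
#' the latent state (active/inactive PSII pools under the inactive-pool
#' damage-repair model, Y(NPQ) induction/relaxation, qP light saturation) is
#' generated first, then mapped to a self-consistent set of fluorescence
#' levels such that the standard definitions recover the latent quantities
#' exactly:
#' \itemize{
#'   \item all unquenched levels scale with the active fraction
#'     `A(t)/active_t0` (photoinactivated centres contribute no variable
#'     fluorescence);
#'   \item the FM' quench ratio is solved so that `FS/FM' - FS/FM` equals
#'     the latent Y(NPQ), with FS positioned between F0' and FM' by the
#'     latent qP;
#'   \item NPQ downregulates `sigma_PSII'` and the antenna contribution to
#'     F0' by the same factor, so `F0'_Oxborough / sigma_PSII'` is exactly
#'     proportional to the true active PSII content;
#'   \item accumulated photoinactivation raises the 2-s-dark F0' estimates
#'     (and hence the corrected F0' used for qP) in proportion to the
#'     inactive fraction, but not the Oxborough estimator.
#' }
#' Lincomycin blocks repair (`k_recinact = 0`); DTT blocks the slow
#' zero-order NPQ phase (`k_npqslow = 0`). Observation noise is applied
#' last, as one multiplicative error per FRR induction trace: the levels
#' extracted from a single induction (the dark-reference pair `f0`/`fm`,
#' the under-light triple `fs`/`fm_prime`/`sigma_psii_prime`, and the
#' 2-s-dark pair) share a calibration/fit error, while errors are
#' independent between inductions and between intervals.
#'
#' @param truth A [kinetic_ground_truth()].
#' @param program A [light_program()] containing at least one treatment
#'   phase.
#' @param inhibitor One of `"none"`, `"lincomycin"`, `"DTT"`.
#' @param noise A [noise_spec()].
#' @param sample_id Identifier recorded on every row.
#' @return A tibble of class `time_course` with one row per measurement
#'   interval: schema columns `sample_id`, `condition`, `inhibitor`,
#'   `interval_index`, `phase`, `t_s`, `t_treat_s`, `t_cum_s`,
#'   `t_recovery_s`, `irradiance_umol`, the measured levels `f0`, `fm`,
#'   `fs`, `fm_prime`, `fm_prime_2s`, `f0_prime_2s`,
#'   `sigma_psii_prime_A2`, and the latent truth columns
#'   `psii_active_true`, `psii_inactive_true`, `y_npq_true`, `qp_true`.
#' @examples
#' tc <- simulate_time_course(kinetic_ground_truth(),
#'                            standard_light_program(97),
#'                            noise = noise_free())
#' @export
simulate_time_course <- function(truth, program,
                                 inhibitor = c("none", "lincomycin", "DTT"),
                                 noise = noise_spec(),
                                 sample_id = "sim") {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  inhibitor <- match.arg(inhibitor)
  if (!inherits(program, "light_program")) {
    stop_invalid("`program` must be a light_program.")
  }
  if (!any(program$phase == "treatment")) {
    stop_invalid("`program` must contain at least one treatment phase.")
  }

  lat <- latent_time_course(truth, program, inhibitor)
  total <- truth$active_t0 + truth$inactive_t0
  a_rel <- lat$psii_active_true / truth$active_t0
  i_rel <- (lat$psii_inactive_true - truth$inactive_t0) / total
  rise_term <- truth$f0_rise * pmax(i_rel, 0)

  u <- purrr::map_dbl(seq_len(nrow(lat)), function(i) {
    solve_quench_ratio(lat$y_npq_true[i], lat$qp_true[i],
                       truth$f0, truth$fm, rise_term[i])
  })

  k_u <- 1 / (1 / truth$f0 - 1 / truth$fm + u / truth$fm)
  f0_row <- truth$f0 * a_rel
  fm_row <- truth$fm * a_rel
  fm_prime <- fm_row / u
  f0_prime_true <- a_rel *
    f0_prime_per_active(u, truth$f0, truth$fm, rise_term)
  fs <- fm_prime - lat$qp_true * (fm_prime - f0_prime_true)
  # partial NPQ relaxation during the 2-s dark period
  u_2s <- 1 + (u - 1) * (1 - truth$npq_relax_2s)
  fm_prime_2s <- fm_row / u_2s
  f0_prime_2s <- f0_prime_true * fm_prime_2s / fm_prime
  sigma_prime <- truth$sigma_psii * k_u / truth$f0

  out <- dplyr::bind_cols(
    tibble(sample_id = sample_id,
           condition = "simulated",
           inhibitor = inhibitor),
    lat[, c("interval_index", "phase", "t_s", "t_treat_s", "t_cum_s",
            "t_recovery_s", "irradiance_umol")],
    {
      # one shared multiplicative error per FRR induction per interval
      eps_dark <- noise_factors(noise, nrow(lat), salt = 1L)
      eps_light <- noise_factors(noise, nrow(lat), salt = 2L)
      eps_2s <- noise_factors(noise, nrow(lat), salt = 3L)
      tibble(
        f0 = f0_row * eps_dark,
        fm = fm_row * eps_dark,
        fs = fs * eps_light,
        fm_prime = fm_prime * eps_light,
        fm_prime_2s = fm_prime_2s * eps_2s,
        f0_prime_2s = f0_prime_2s * eps_2s,
        sigma_psii_prime_A2 = sigma_prime * eps_light
      )
    },
    lat[, c("psii_active_true", "psii_inactive_true", "y_npq_true",
            "qp_true")]
  )
  class(out) <- c("time_course", class(out))
  out
}

#' Derive quenching parameters for a simulated or measured time course
#'
#' Convenience wrapper around [derive_yields()] that maps the
#' `timecourse.csv` column names (`sigma_psii_prime_A2`) onto the generic
#' yield-set names and appends all derived quantities, including the
#' activity proxy `F0'_Oxborough / sigma_PSII'`.
#'
#' @param data A time-course data frame (see [simulate_time_course()]).
#' @return The input tibble with derived columns appended.
#' @export
derive_time_course <- function(data) {
  if (!"sigma_psii_prime_A2" %in% names(data)) {
    stop_invalid("`data` must contain `sigma_psii_prime_A2`.")
  }
  data <- dplyr::mutate(as_tibble(data),
                        sigma_psii_prime = .data$sigma_psii_prime_A2)
  derive_yields(data)
}
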