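#' 2-s-dark-corrected estimate of F0'
#'
#' The minimal fluorescence under illumination, F0', cannot be read directly
#' while actinic light is on. It is instead measured 2 s after excitation
#' (F0'_2s) and corrected for the partial relaxation of non-photochemical
#' quenching during those 2 s, using the concurrent rise from FM' to FM'_2s:
#' `F0' = F0'_2s * (1 - (FM'_2s - FM') / FM'_2s) = F0'_2s * FM' / FM'_2s`.
#' This estimator retains the F0 rise caused by accumulated
#' photoinactivation; contrast [f0_prime_oxborough()].
#'
#' @param f0_prime_2s Minimal fluorescence 2 s after excitation.
#' @param fm_prime Maximal fluorescence under excitation.
#' @param fm_prime_2s Maximal fluorescence 2 s after excitation.
#' @return Corrected F0' estimate. Vectorised.
#' @examples
#' correct_f0_prime(0.9, 2, 3) # 0.6
#' @export
correct_f0_prime <- function(f0_prime_2s, fm_prime, fm_prime_2s) {
  if (any(f0_prime_2s <= 0) || any(fm_prime <= 0) || any(fm_prime_2s <= 0)) {
    stop_invalid("All fluorescence levels must be > 0.")
  }
  f0_prime_2s * fm_prime / fm_prime_2s
}

#' Oxborough-Baker estimate of F0'
#'
#' `F0'_Oxborough = 1 / (1/F0 - 1/FM + 1/FM')`. Corrects the dark-acclimated
#' F0 for non-photochemical quenching of the antenna but, because it is
#' built only from F0, FM and FM', excludes the cumulative F0 rise caused by
#' photoinactivated centres. That exclusion is what makes
#' `F0'_Oxborough / sigma_PSII'` a proxy for active PSII content that stays
#' linear in the face of accumulated photoinactivation.
#'
#' @param f0 Dark-acclimated minimal fluorescence.
#' @param fm Dark-acclimated maximal fluorescence; must exceed `f0`.
#' @param fm_prime Maximal fluorescence under excitation.
#' @return F0' estimate. Vectorised.
#' @examples
#' f0_prime_oxborough(1, 4, 2) # 0.8
#' @export
f0_prime_oxborough <- function(f0, fm, fm_prime) {
  if (any(f0 <= 0) || any(fm <= 0) || any(fm_prime <= 0)) {
    stop_invalid("All fluorescence levels must be > 0.")
  }
  if (any(fm <= f0)) stop_invalid("`fm` must exceed `f0`.")
  den <- 1 / f0 - 1 / fm + 1 / fm_prime
  if (any(den <= 0)) {
    stop_invalid("Denominator 1/f0 - 1/fm + 1/fm_prime must be > 0.")
  }
  1 / den
}

#' Fluorescence proxy for active PSII content
#'
#' The ratio `F0'_Oxborough / sigma_PSII'`. Both numerator and denominator
#' are quenched in proportion by NPQ acting on the shared light-harvesting
#' antenna, so their ratio tracks the number of photochemically competent
#' PSII and can be calibrated against oxygen flash-yield counts of active
#' PSII (see [fit_proxy_calibration()]).
#'
#' @param f0_prime_ox Oxborough-Baker F0' estimate, relative fluorescence.
#' @param sigma_psii_prime Effective absorbance cross section under
#'   excitation, A^2 quanta^-1.
#' @return Proxy value, relative fluorescence per A^2 quanta^-1. Vectorised.
#' @export
psii_activity_proxy <- function(f0_prime_ox, sigma_psii_prime) {
  if (any(sigma_psii_prime <= 0)) stop_invalid("`sigma_psii_prime` must be > 0.")
  f0_prime_ox / sigma_psii_prime
}

#' PSII electron transport rate
#'
#' `PSII_ETR = sigma_PSII / (FV/FM) * Y(PSII) * I`, in electrons PSII^-1
#' s^-1, with the cross section converted from A^2 to m^2 and the irradiance
#' from umol photons to photons m^-2 s^-1.
#'
#' @param sigma_psii Cross section, A^2 quanta^-1.
#' @param fv_fm Dark-acclimated maximal photochemical yield, (fm-f0)/fm.
#' @param y_psii Quantum yield of PSII photochemistry under excitation.
#' @param irradiance Irradiance, umol photons m^-2 s^-1.
#' @return Electron transport rate, e- PSII^-1 s^-1. Vectorised.
#' @examples
#' psii_etr(500, 0.5, 0.25, 100) # ~150.6
#' @export
psii_etr <- function(sigma_psii, fv_fm, y_psii, irradiance) {
  if (any(fv_fm <= 0)) stop_invalid("`fv_fm` must be > 0.")
  a2_to_m2(sigma_psii) / fv_fm * y_psii * photon_flux(irradiance)
}

#' Derive the full set of quenching and yield parameters
#'
#' Takes a data frame of per-measurement FRR fluorescence levels and appends
#' every derived quantity:
#' `NPQ = (FM - FM')/FM'`, `Y(PSII) = (FM' - FS)/FM'`, `Y(NO) = FS/FM`,
#' `Y(NPQ) = FS/FM' - FS/FM`, `qP = (FM' - FS)/(FM' - F0')`,
#' `FV/FM = (FM - F0)/FM`, the two F0' estimators, and, when the relevant
#' columns are present, the activity proxy and the PSII electron transport
#' rate. The three quantum yields satisfy the exact partition
#' `Y(PSII) + Y(NO) + Y(NPQ) = 1`.
#'
#' `FS` slightly outside `[F0', FM']` (within 2 % of either bound) is
#' clipped with a warning, as measurement noise routinely produces such
#' values; larger violations are errors.
#'
#' @param data A data frame with columns `f0`, `fm`, `fs`, `fm_prime`,
#'   `fm_prime_2s`, `f0_prime_2s`, and optionally `sigma_psii_prime` and
#'   `irradiance_umol`. Extra columns pass through.
#' @return A tibble: the input plus columns `f0_prime`, `f0_prime_ox`,
#'   `fv_fm`, `npq`, `y_psii`, `y_no`, `y_npq`, `qp`, and (when inputs
#'   allow) `proxy` and `psii_etr`.
#' @examples
#' derive_yields(tibble::tibble(
#'   f0 = 1, fm = 4, fs = 1.5, fm_prime = 2,
#'   fm_prime_2s = 2, f0_prime_2s = 0.8
#' ))
#' @export
derive_yields <- function(data) {
  need <- c("f0", "fm", "fs", "fm_prime", "fm_prime_2s", "f0_prime_2s")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_invalid(paste0("`data` is missing columns: ",
                        paste(miss, collapse = ", "), "."))
  }
  out <- as_tibble(data)
  out$f0_prime <- correct_f0_prime(out$f0_prime_2s, out$fm_prime,
                                   out$fm_prime_2s)
  out$f0_prime_ox <- f0_prime_oxborough(out$f0, out$fm, out$fm_prime)
  if (any(out$fm_prime <= out$f0_prime)) {
    stop_invalid("`fm_prime` must exceed the corrected `f0_prime` (qP undefined).")
  }

  # clip fs to [f0_prime, fm_prime] within a 2 % noise tolerance
  lo <- out$f0_prime
  hi <- out$fm_prime
  fs <- out$fs
  below <- fs < lo * (1 - 1e-9)   # beyond float round-off
  above <- fs > hi * (1 + 1e-9)
  if (any(fs < lo * 0.98) || any(fs > hi * 1.02)) {
    stop_invalid("`fs` lies more than 2 % outside [f0_prime, fm_prime].")
  }
  if (any(below | above)) {
    warn("`fs` slightly outside [f0_prime, fm_prime]; clipped to the bound.")
  }
  fs <- pmin(pmax(fs, lo), hi)

  out$fv_fm <- (out$fm - out$f0) / out$fm
  out$npq <- (out$fm - out$fm_prime) / out$fm_prime
  out$y_psii <- (out$fm_prime - fs) / out$fm_prime
  out$y_no <- fs / out$fm
  out$y_npq <- fs / out$fm_prime - fs / out$fm
  out$qp <- (out$fm_prime - fs) / (out$fm_prime - out$f0_prime)

  if ("sigma_psii_prime" %in% names(out)) {
    out$proxy <- psii_activity_proxy(out$f0_prime_ox, out$sigma_psii_prime)
  }
  if (all(c("sigma_psii_prime", "irradiance_umol") %in% names(out))) {
    out$psii_etr <- psii_etr(out$sigma_psii_prime, out$fv_fm, out$y_psii,
                             out$irradiance_umol)
  }
  out
}
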