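#' Physical and protocol constants
#'
#' Unit constants used throughout the package. All unit conversions funnel
#' through these helpers so that the Angstrom-squared / square-metre and
#' mole / photon conversions live in exactly one place.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{a2_per_m2}{Square Angstroms per square metre (1e20).}
#'   \item{o2_per_flash_per_psii}{Flashes required to evolve one O2 per
#'     active PSII: 4, from the four-step S-state cycle of the
#'     oxygen-evolving complex.}
#'   \item{default_flash_hz}{Single-turnover flash-train frequency implied
#'     by a 25-us flash followed by 25-ms darkness: 1/(25.025e-3) = 39.96 Hz.}
#' }
#' @export
psii_constants <- list(
  avogadro            = 6.02214076e23,
  a2_per_m2           = 1e20,
  o2_per_flash_per_psii = 4,
  default_flash_hz    = 1 / (25e-6 + 25e-3)
)

#' Convert irradiance to photon flux
#'
#' Converts an irradiance in umol photons m^-2 s^-1 (the unit at every data
#' interface) to photons m^-2 s^-1, the unit required when multiplying by a
#' target size in m^2 photon^-1.
#'
#' @param irradiance Irradiance, umol photons m^-2 s^-1. Vectorised.
#' @return Photon flux, photons m^-2 s^-1.
#' @examples
#' photon_flux(100) # 6.022e19
#' @export
photon_flux <- function(irradiance) {
  if (any(irradiance < 0)) {
    stop_invalid("`irradiance` must be non-negative.")
  }
  irradiance * 1e-6 * psii_constants$avogadro
}

#' Convert a cross section from square Angstroms to square metres
#'
#' @param sigma_a2 Cross section, A^2 quanta^-1.
#' @return Cross section, m^2 quanta^-1.
#' @export
a2_to_m2 <- function(sigma_a2) {
  sigma_a2 / psii_constants$a2_per_m2
}
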