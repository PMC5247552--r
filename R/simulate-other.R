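#' Simulate an oxygen-optode trace with a single-turnover flash train
#'
#' Piecewise-linear O2 concentration over a labelled phase program: during
#' dark (and pre-illumination) phases the slope is `-respiration`; during a
#' flash-train phase each saturating single-turnover flash advances every
#' active PSII one S-state step, evolving one O2 per four flashes per PSII,
#' so the slope is `-respiration + psii_conc * flash_frequency / 4`.
#'
#' @param psii_conc Active PSII concentration, umol L^-1.
#' @param respiration Dark respiration rate, umol O2 L^-1 s^-1 (>= 0).
#' @param flash_frequency Flash-train frequency, Hz. The protocol default,
#'   a 25-us flash followed by 25-ms darkness, gives
#'   `psii_constants$default_flash_hz` (39.96 Hz).
#' @param phases A data frame with columns `phase` (labels such as
#'   `"dark_pre"`, `"preillumination"`, `"flash_train"`, `"dark_post"`,
#'   `"treatment"`) and `duration` (s). Any phase labelled `"flash_train"`
#'   receives the flash-yield slope; all others the respiration slope.
#' @param noise A [noise_spec()]; multiplicative noise on concentration.
#' @param o2_start Starting O2 concentration, umol L^-1 (default 250).
#' @param sample_hz Optode sampling rate, Hz (default 1).
#' @return A tibble of class `o2_trace` with columns `time_s`,
#'   `o2_umol_per_L`, `phase`.
#' @examples
#' ph <- tibble::tibble(
#'   phase = c("dark_pre", "flash_train", "dark_post"),
#'   duration = c(300, 240, 300)
#' )
#' simulate_o2_trace(2e-3, 0.01, phases = ph, noise = noise_free())
#' @export
simulate_o2_trace <- function(psii_conc, respiration,
                              flash_frequency = psii_constants$default_flash_hz,
                              phases, noise = noise_spec(0.005),
                              o2_start = 250, sample_hz = 1) {
  if (flash_frequency <= 0) stop_invalid("`flash_frequency` must be > 0.")
  if (psii_conc < 0) stop_invalid("`psii_conc` must be >= 0.")
  if (respiration < 0) stop_invalid("`respiration` must be >= 0.")
  if (!all(c("phase", "duration") %in% names(phases))) {
    stop_invalid("`phases` must have columns `phase` and `duration`.")
  }
  if (any(phases$duration <= 0)) stop_invalid("Phase durations must be > 0.")

  flash_slope <- -respiration +
    psii_conc * flash_frequency / psii_constants$o2_per_flash_per_psii

  t0 <- 0
  o2 <- o2_start
  segs <- vector("list", nrow(phases))
  for (p in seq_len(nrow(phases))) {
    slope <- if (phases$phase[p] == "flash_train") flash_slope else -respiration
    tt <- seq(0, phases$duration[p], by = 1 / sample_hz)
    segs[[p]] <- tibble(
      time_s = t0 + tt,
      o2_umol_per_L = o2 + slope * tt,
      phase = phases$phase[p]
    )
    t0 <- t0 + phases$duration[p]
    o2 <- o2 + slope * phases$duration[p]
  }
  out <- dplyr::bind_rows(segs)
  out$o2_umol_per_L <- apply_noise(out$o2_umol_per_L, noise)
  class(out) <- c("o2_trace", class(out))
  out
}

#' Simulate first-order PsbA protein decay
#'
#' Under lincomycin, no new PsbA is synthesised and the existing pool is
#' cleared proteolytically: `P(t) = p0 * exp(-k_psba * t)`.
#'
#' @param p0 Initial PsbA content, fmol (ug protein)^-1 (> 0).
#' @param k_psba Clearance rate constant, s^-1 (>= 0).
#' @param times Sampling times, s.
#' @param noise A [noise_spec()].
#' @return A tibble with columns `time_s`, `psba_fmol_per_ug`.
#' @export
simulate_psba_course <- function(p0, k_psba, times, noise = noise_spec()) {
  if (p0 <= 0) stop_invalid("`p0` must be > 0.")
  if (k_psba < 0) stop_invalid("`k_psba` must be >= 0.")
  tibble(
    time_s = times,
    psba_fmol_per_ug = apply_noise(p0 * exp(-k_psba * times), noise)
  )
}

# Gaussian band in wavelength space
gaussian_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Simulate whole-cell absorbance spectra as sums of pigment bands
#'
#' Builds replicate whole-cell spectra from Gaussian pigment bands: the
#' chlorophyll a red band (674 nm), the Soret band (435 nm), a chlorophyll b
#' shoulder (470 nm), and the carotenoid region including the zeaxanthin
#' (485 nm) and lutein (494 nm) bands whose relative amplitudes report
#' xanthophyll-cycle state.
#'
#' @param band_amplitudes Named numeric vector of band amplitudes on a
#'   relative scale; names among `chl_red`, `soret`, `chl_b`, `lutein`.
#'   Missing entries take the defaults
#'   `c(chl_red = 1, soret = 1.6, chl_b = 0.8, lutein = 0.35)`.
#' @param zeaxanthin_amp Amplitude of the 485-nm zeaxanthin band.
#' @param grid Wavelength grid, nm; must cover 400-750 nm (and so the
#'   673-675-nm red-peak window).
#' @param noise A [noise_spec()]. The multiplicative CV is applied as
#'   independent per-band amplitude jitter for each replicate (emulating
#'   replicate-to-replicate variation in pigment content, the dominant
#'   variance component between independently grown cultures), and
#'   `additive_sd` as per-point white instrument noise in `a` units. White
#'   noise is heavily amplified by second differentiation, so its default
#'   is small.
#' @param n_replicates Number of replicate spectra (default 3).
#' @param chl_ug_per_L Chlorophyll a concentration attached to each
#'   spectrum, ug chl L^-1.
#' @param band_widths Named numeric vector of Gaussian widths (nm) with the
#'   same names plus `zeaxanthin`; defaults
#'   `c(chl_red = 10, soret = 18, chl_b = 12, zeaxanthin = 4, lutein = 4)`.
#' @return A tibble of class `absorbance_spectra` with columns
#'   `replicate_id`, `wavelength_nm`, `a_per_m`, `chl_ug_per_L`.
#' @examples
#' sp <- simulate_spectra(noise = noise_free())
#' @export
simulate_spectra <- function(band_amplitudes = NULL,
                             zeaxanthin_amp = 0.4,
                             grid = seq(400, 750, by = 1),
                             noise = noise_spec(0.02, additive_sd = 2e-3),
                             n_replicates = 3,
                             chl_ug_per_L = 100,
                             band_widths = NULL) {
  amp <- c(chl_red = 1, soret = 1.6, chl_b = 0.8, lutein = 0.35)
  if (!is.null(band_amplitudes)) {
    amp[names(band_amplitudes)] <- band_amplitudes
  }
  wid <- c(chl_red = 10, soret = 18, chl_b = 12, zeaxanthin = 4, lutein = 4)
  if (!is.null(band_widths)) {
    wid[names(band_widths)] <- band_widths
  }
  if (min(grid) > 400 || max(grid) < 750) {
    stop_invalid("`grid` must cover 400-750 nm.")
  }
  if (zeaxanthin_amp < 0) stop_invalid("`zeaxanthin_amp` must be >= 0.")

  centers <- c(chl_red = 674, soret = 435, chl_b = 470,
               zeaxanthin = 485, lutein = 494)
  amps <- c(amp["chl_red"], amp["soret"], amp["chl_b"],
            zeaxanthin = unname(zeaxanthin_amp), amp["lutein"])

  out <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    withr::with_seed(noise$seed + r, {
      jitter <- 1 + rnorm(length(amps), 0, noise$multiplicative_cv)
      white <- rnorm(length(grid), 0, noise$additive_sd)
    })
    a <- white
    for (b in names(centers)) {
      a <- a + gaussian_band(grid, centers[[b]], wid[[b]],
                             amps[[b]] * jitter[[match(b, names(centers))]])
    }
    tibble(
      replicate_id = r,
      wavelength_nm = grid,
      a_per_m = pmax(a, 0),
      chl_ug_per_L = chl_ug_per_L
    )
  })
  class(out) <- c("absorbance_spectra", class(out))
  out
}
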