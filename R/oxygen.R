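#' Per-phase linear slopes of an oxygen-optode trace
#'
#' Fits an ordinary least-squares line to the O2 concentration within each
#' labelled phase of a trace and returns the slopes, in umol O2 L^-1 s^-1.
#' The difference between the flash-train slope and the immediately
#' following dark slope is the net O2 evolution rate of the flash train.
#'
#' @param trace A data frame with columns `time_s`, `o2_umol_per_L`,
#'   `phase` (see [simulate_o2_trace()]); each phase needs >= 5 samples.
#' @return A tibble with columns `phase`, `slope`, `intercept`, `n`, in
#'   trace order.
#' @export
segment_and_slopes <- function(trace) {
  need <- c("time_s", "o2_umol_per_L", "phase")
  if (!all(need %in% names(trace))) {
    stop_invalid(paste0("`trace` must have columns: ",
                        paste(need, collapse = ", "), "."))
  }
  d <- as_tibble(trace)
  phases <- unique(d$phase)
  purrr::map_dfr(phases, function(ph) {
    seg <- d[d$phase == ph, ]
    if (nrow(seg) < 5) {
      stop_invalid(paste0("Phase `", ph, "` has fewer than 5 samples."))
    }
    fit <- lm(o2_umol_per_L ~ time_s, data = seg)
    tibble(phase = ph, slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]), n = nrow(seg))
  })
}

#' Active PSII concentration from oxygen flash yields
#'
#' A train of saturating single-turnover flashes advances every active PSII
#' one S-state step per flash, evolving one O2 per four flashes per centre.
#' The O2 evolution attributable to the flash train is the flash-train slope
#' minus the respiration slope measured in the darkness immediately after
#' the train, so
#' `[PSII]_active = 4 * (slope_flash - slope_dark_post) / flash_frequency`.
#'
#' @param slope_flash O2 slope during the flash train, umol L^-1 s^-1.
#' @param slope_dark_post O2 slope in the darkness immediately after the
#'   train (the respiration reference), umol L^-1 s^-1.
#' @param flash_frequency Flash frequency, Hz (default 39.96, from the
#'   25-us flash + 25-ms dark protocol).
#' @return Active PSII concentration, umol L^-1. A flash slope below the
#'   dark slope is clamped to 0 with a warning.
#' @examples
#' psii_from_flash_yield(0.01, -0.01) # ~2.002e-3
#' @export
psii_from_flash_yield <- function(slope_flash, slope_dark_post,
                                  flash_frequency = psii_constants$default_flash_hz) {
  if (flash_frequency <= 0) stop_invalid("`flash_frequency` must be > 0.")
  diff_slope <- slope_flash - slope_dark_post
  if (any(diff_slope < 0)) {
    warn("Flash-train slope below dark slope; [PSII]active clamped at 0.")
    diff_slope <- pmax(diff_slope, 0)
  }
  psii_constants$o2_per_flash_per_psii * diff_slope / flash_frequency
}

#' Calibrate the fluorescence proxy against flash-yield PSII counts
#'
#' Ordinary least-squares regression (with intercept) of the
#' `F0'_Oxborough / sigma_PSII'` proxy on oxygen flash-yield measures of
#' active PSII taken on the same samples. The returned line converts the
#' rapid, non-invasive fluorescence proxy into absolute active-PSII units.
#'
#' @param data A data frame with columns `psii_active` (flash-yield
#'   measure, x) and `proxy` (fluorescence proxy, y); >= 3 points.
#' @return An object of class `calibration_line`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, and the `lm` fit.
#' @export
fit_proxy_calibration <- function(data) {
  if (!all(c("psii_active", "proxy") %in% names(data))) {
    stop_invalid("`data` must have columns `psii_active` and `proxy`.")
  }
  d <- as_tibble(data)
  if (nrow(d) < 3) stop_invalid("Need >= 3 calibration points.")
  if (sd(d$psii_active) == 0) {
    stop_invalid("Zero variance in `psii_active`: calibration undefined.")
  }
  fit <- lm(proxy ~ psii_active, data = d)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         n = nrow(d),
         fit = fit),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat("<calibration_line>\n")
  cat(sprintf("  proxy = %.6g * [PSII]active + %.6g   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Initial inactive-PSII pool from protein and activity measures
#'
#' Estimates the pool of photoinactivated-but-intact PSII present under
#' growth conditions as the excess of total PsbA protein content over the
#' oxygen-flash-yield count of active PSII:
#' `inactive_t0 = max(psba - active, 0)`. A negative difference (active
#' apparently exceeding PsbA, within measurement error) is clamped to 0 and
#' flagged via the `"clamped"` attribute.
#'
#' @param psba Total PsbA content, fmol (ug protein)^-1.
#' @param active Active PSII content, fmol (ug protein)^-1.
#' @return Inactive pool estimate (same units), with attribute `clamped`.
#' @examples
#' estimate_initial_inactive_pool(79, 42)  # 37
#' estimate_initial_inactive_pool(112, 133) # 0 (clamped)
#' @export
estimate_initial_inactive_pool <- function(psba, active) {
  if (any(psba < 0) || any(active < 0)) {
    stop_invalid("`psba` and `active` must be >= 0.")
  }
  raw <- psba - active
  out <- pmax(raw, 0)
  attr(out, "clamped") <- raw < 0
  out
}

#' Exponential growth rate from in vivo chlorophyll fluorescence
#'
#' The growth rate mu (d^-1) is the least-squares slope of
#' `ln(F680)` versus elapsed time in days, F680 being the bulk chlorophyll a
#' fluorescence of the culture.
#'
#' @param data A data frame with columns `time_d` and `f680` (> 0);
#'   >= 3 points.
#' @return Growth rate, d^-1.
#' @examples
#' growth_rate(tibble::tibble(time_d = 0:5, f680 = 2^(0:5))) # ln 2
#' @export
growth_rate <- function(data) {
  if (!all(c("time_d", "f680") %in% names(data))) {
    stop_invalid("`data` must have columns `time_d` and `f680`.")
  }
  d <- as_tibble(data)
  if (nrow(d) < 3) stop_invalid("Need >= 3 points.")
  if (any(d$f680 <= 0)) stop_invalid("`f680` must be > 0.")
  unname(coef(lm(log(f680) ~ time_d, data = d))[2])
}
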