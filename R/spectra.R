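#' Normalise whole-cell spectra to the red chlorophyll a peak
#'
#' Divides each replicate spectrum by its maximum absorbance within the
#' 673-675-nm window, so spectra of cultures at different biomass become
#' comparable. Idempotent, and invariant to rescaling the input.
#'
#' @param data A data frame with columns `wavelength_nm`, `a_per_m` and
#'   optionally `replicate_id` (normalisation is per replicate). The grid
#'   must cover 670-680 nm.
#' @return The input tibble with `a_per_m` replaced by the normalised
#'   values (peak value 1 within 673-675 nm).
#' @export
normalize_to_red_peak <- function(data) {
  check_spectrum_cols(data)
  d <- as_tibble(data)
  if (min(d$wavelength_nm) > 670 || max(d$wavelength_nm) < 680) {
    stop_invalid("Wavelength grid must cover 670-680 nm.")
  }
  if (!"replicate_id" %in% names(d)) d$replicate_id <- 1L
  d |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(g, key) {
      win <- g$a_per_m[g$wavelength_nm >= 673 & g$wavelength_nm <= 675]
      peak <- max(win)
      if (peak <= 0) {
        stop_invalid("Zero absorbance in the 673-675-nm red-peak window.")
      }
      g$a_per_m <- g$a_per_m / peak
      g
    }) |>
    dplyr::ungroup()
}

check_spectrum_cols <- function(data) {
  if (!all(c("wavelength_nm", "a_per_m") %in% names(data))) {
    stop_invalid("Spectra need columns `wavelength_nm` and `a_per_m`.")
  }
  invisible(TRUE)
}

#' Second derivative of a spectrum on a 2-nm grid
#'
#' Linearly interpolates each replicate spectrum onto a regular 2-nm grid
#' and applies central second differences,
#' `d2[i] = (a[i-1] - 2 a[i] + a[i+1]) / h^2`. No smoothing is applied.
#' Inflection structure in the carotenoid region shows up as local minima
#' of the second derivative at the band centres.
#'
#' @param data A data frame with `wavelength_nm`, `a_per_m`, optional
#'   `replicate_id`; the native grid spacing must be <= 2 nm.
#' @param step_nm Interpolation step, nm (default 2).
#' @return A tibble with columns `replicate_id`, `wavelength_nm`,
#'   `d2` (second derivative, per nm^2).
#' @export
second_derivative <- function(data, step_nm = 2) {
  check_spectrum_cols(data)
  d <- as_tibble(data)
  if (!"replicate_id" %in% names(d)) d$replicate_id <- 1L
  purrr::map_dfr(unique(d$replicate_id), function(r) {
    g <- d[d$replicate_id == r, ]
    g <- g[order(g$wavelength_nm), ]
    if (max(diff(g$wavelength_nm)) > step_nm + 1e-9) {
      stop_invalid("Native wavelength grid coarser than the interpolation step.")
    }
    wl <- seq(min(g$wavelength_nm), max(g$wavelength_nm), by = step_nm)
    a <- approx(g$wavelength_nm, g$a_per_m, xout = wl)$y
    n <- length(wl)
    d2 <- (a[1:(n - 2)] - 2 * a[2:(n - 1)] + a[3:n]) / step_nm^2
    tibble(replicate_id = r, wavelength_nm = wl[2:(n - 1)], d2 = d2)
  })
}

#' Normalise second-derivative spectra to the red-peak trough
#'
#' Divides each replicate's second derivative by the absolute value of its
#' most negative point within 677-679 nm (the chlorophyll a red-band
#' trough), so that point becomes exactly -1 and replicate spectra become
#' amplitude-comparable.
#'
#' @param data Output of [second_derivative()].
#' @return The input with `d2` normalised per replicate.
#' @export
normalize_second_derivative <- function(data) {
  if (!all(c("wavelength_nm", "d2") %in% names(data))) {
    stop_invalid("`data` must have columns `wavelength_nm` and `d2`.")
  }
  d <- as_tibble(data)
  if (!"replicate_id" %in% names(d)) d$replicate_id <- 1L
  purrr::map_dfr(unique(d$replicate_id), function(r) {
    g <- d[d$replicate_id == r, ]
    win <- g$d2[g$wavelength_nm >= 677 & g$wavelength_nm <= 679]
    if (length(win) == 0 || min(win) >= 0) {
      stop_invalid("No negative second-derivative value in 677-679 nm.")
    }
    g$d2 <- g$d2 / abs(min(win))
    g
  })
}

#' Average replicate spectra with pointwise confidence intervals
#'
#' Pointwise mean and 95 % t-interval across replicate spectra on a common
#' wavelength grid.
#'
#' @param data A data frame with `replicate_id`, `wavelength_nm` and a
#'   value column (`a_per_m` or `d2`); >= 2 replicates on identical grids.
#' @param value Name of the value column (default auto-detected).
#' @return A tibble with `wavelength_nm`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
average_replicates <- function(data, value = NULL) {
  d <- as_tibble(data)
  if (is.null(value)) {
    value <- if ("d2" %in% names(d)) "d2" else "a_per_m"
  }
  if (!all(c("replicate_id", "wavelength_nm", value) %in% names(d))) {
    stop_invalid("`data` must have `replicate_id`, `wavelength_nm` and the value column.")
  }
  if (length(unique(d$replicate_id)) < 2) {
    stop_invalid("Need >= 2 replicates.")
  }
  grids <- split(d$wavelength_nm, d$replicate_id)
  if (!all(vapply(grids, function(g) identical(sort(g), sort(grids[[1]])),
                  logical(1)))) {
    stop_invalid("Replicates are not on a common wavelength grid.")
  }
  d |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      se = sd(.data[[value]]) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lo = .data$mean - qt(0.975, .data$n - 1) * .data$se,
      ci_hi = .data$mean + qt(0.975, .data$n - 1) * .data$se
    ) |>
    dplyr::select("wavelength_nm", "mean", "ci_lo", "ci_hi", "n")
}

#' Compare a carotenoid-region band between two groups of spectra
#'
#' Per-wavelength two-sample Welch t-tests across a wavelength window
#' (default the 470-500-nm carotenoid region, where the zeaxanthin 485-nm
#' and lutein 494-nm bands report xanthophyll-cycle pigment state), on
#' normalised second-derivative replicate spectra. Raw pointwise p-values
#' are reported alongside Holm-adjusted ones; the significance mask uses
#' the raw p-values at level `alpha`.
#'
#' @param group_a,group_b Data frames of replicate spectra with
#'   `replicate_id`, `wavelength_nm` and a common value column (`d2` or
#'   `a_per_m`); >= 3 replicates per group recommended, >= 2 required.
#' @param window Length-2 numeric window in nm (default `c(470, 500)`).
#' @param alpha Significance level for the mask (default 0.05).
#' @param value Value column name (default auto-detected).
#' @return A tibble of class `band_comparison` with columns
#'   `wavelength_nm`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `p_holm`, `significant`.
#' @export
compare_band <- function(group_a, group_b, window = c(470, 500),
                         alpha = 0.05, value = NULL) {
  a <- as_tibble(group_a)
  b <- as_tibble(group_b)
  if (is.null(value)) value <- if ("d2" %in% names(a)) "d2" else "a_per_m"
  for (g in list(a, b)) {
    if (!all(c("replicate_id", "wavelength_nm", value) %in% names(g))) {
      stop_invalid("Groups need `replicate_id`, `wavelength_nm` and the value column.")
    }
    if (length(unique(g$replicate_id)) < 2) {
      stop_invalid("Each group needs >= 2 replicates.")
    }
  }
  wls <- sort(intersect(
    unique(a$wavelength_nm[a$wavelength_nm >= window[1] &
                             a$wavelength_nm <= window[2]]),
    unique(b$wavelength_nm[b$wavelength_nm >= window[1] &
                             b$wavelength_nm <= window[2]])
  ))
  if (length(wls) == 0) stop_invalid("No common wavelengths in the window.")
  out <- purrr::map_dfr(wls, function(w) {
    xa <- a[[value]][a$wavelength_nm == w]
    xb <- b[[value]][b$wavelength_nm == w]
    tt <- t.test(xa, xb)
    tibble(wavelength_nm = w, mean_a = mean(xa), mean_b = mean(xb),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_value < alpha
  class(out) <- c("band_comparison", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Chlorophyll-specific absorption coefficient over 400-700 nm
#'
#' The spectrally averaged absorption coefficient per unit chlorophyll a,
#' `a* = mean(a(lambda), 400-700 nm) / chl`, in m^2 (mg chl)^-1 with `chl`
#' expressed in mg m^-3 (numerically equal to ug L^-1). A trapezoidal
#' spectral integral divided by the 300-nm bandwidth is available as an
#' alternative to the plain grid mean.
#'
#' @param data A data frame with `wavelength_nm`, `a_per_m` and
#'   `chl_ug_per_L` (single spectrum, or per `replicate_id` when present).
#' @param method `"mean"` (default) or `"integral"` (trapezoidal, divided
#'   by the bandwidth; identical on a uniform grid).
#' @return A tibble with `replicate_id` and `a_star_m2_per_mg`.
#' @export
chl_specific_absorption <- function(data, method = c("mean", "integral")) {
  method <- match.arg(method)
  check_spectrum_cols(data)
  if (!"chl_ug_per_L" %in% names(data)) {
    stop_invalid("`data` must contain `chl_ug_per_L`.")
  }
  d <- as_tibble(data)
  if (!"replicate_id" %in% names(d)) d$replicate_id <- 1L
  purrr::map_dfr(unique(d$replicate_id), function(r) {
    g <- d[d$replicate_id == r, ]
    g <- g[order(g$wavelength_nm), ]
    if (min(g$wavelength_nm) > 400 || max(g$wavelength_nm) < 700) {
      stop_invalid("Grid must cover 400-700 nm.")
    }
    chl <- g$chl_ug_per_L[1]   # ug L^-1 == mg m^-3
    if (chl <= 0) stop_invalid("`chl_ug_per_L` must be > 0.")
    win <- g[g$wavelength_nm >= 400 & g$wavelength_nm <= 700, ]
    abar <- if (method == "mean") {
      mean(win$a_per_m)
    } else {
      wl <- win$wavelength_nm
      aa <- win$a_per_m
      sum(diff(wl) * (aa[-1] + aa[-length(aa)]) / 2) / (max(wl) - min(wl))
    }
    tibble(replicate_id = r, a_star_m2_per_mg = abar / chl)
  })
}
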