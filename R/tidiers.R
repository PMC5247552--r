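#' Tidy and glance methods for fitted objects
#'
#' Broom-style summaries: `tidy()` returns one row per parameter with its
#' 95 % confidence bounds where available; `glance()` returns a one-row
#' model summary.
#'
#' @param x A `pooled_fit`, `frr_fit`, `reopening_fit` or
#'   `calibration_line`.
#' @param ... Unused.
#' @return A tibble.
#' @name psii_tidiers
NULL

#' @rdname psii_tidiers
#' @export
tidy.pooled_fit <- function(x, ...) {
  tibble(
    term = x$parameter,
    estimate = unname(x$estimate),
    conf.low = x$ci[, 1],
    conf.high = x$ci[, 2]
  )
}

#' @rdname psii_tidiers
#' @export
glance.pooled_fit <- function(x, ...) {
  tibble(model = x$model, n_courses = x$n, nobs = nrow(x$residuals),
         rss = x$rss, flags = paste(x$flags, collapse = ";"))
}

#' @rdname psii_tidiers
#' @export
tidy.frr_fit <- function(x, ...) {
  tibble(
    term = c("f0", "fm", "sigma_psii", "rho"),
    estimate = c(x$f0, x$fm, x$sigma_psii, x$rho)
  )
}

#' @rdname psii_tidiers
#' @export
glance.frr_fit <- function(x, ...) {
  tibble(rmse = x$rmse, nobs = x$n, context = x$context)
}

#' @rdname psii_tidiers
#' @export
tidy.reopening_fit <- function(x, ...) {
  tibble(
    term = c("tau1", "tau2", "fast_fraction"),
    estimate = c(x$tau1, x$tau2, x$fast_fraction)
  )
}

#' @rdname psii_tidiers
#' @export
glance.reopening_fit <- function(x, ...) {
  tibble(rmse = x$rmse, single_phase = x$single_phase)
}

#' @rdname psii_tidiers
#' @export
tidy.calibration_line <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname psii_tidiers
#' @export
glance.calibration_line <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}
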