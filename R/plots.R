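#' Plot a treatment time course
#'
#' Faceted ggplot of the principal derived quantities of a (derived) time
#' course — the active-PSII proxy, Y(NPQ) and qP — against elapsed time,
#' coloured by irradiance phase.
#'
#' @param data A derived time course (see [derive_time_course()]).
#' @param vars Derived columns to facet (default
#'   `c("proxy", "y_npq", "qp")`).
#' @return A ggplot object.
#' @export
plot_time_course <- function(data, vars = c("proxy", "y_npq", "qp")) {
  vars <- intersect(vars, names(data))
  if (length(vars) == 0) {
    stop_invalid("None of the requested columns are present; run derive_time_course() first.")
  }
  long <- tidyr::pivot_longer(as_tibble(data), dplyr::all_of(vars),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s / 60, .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       alpha = 0.4) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, colour = "Phase")
}

#' Plot an FRR induction fit
#'
#' Observed flashlet fluorescence with the fitted cumulative-closure curve
#' overlaid.
#'
#' @param object An `frr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frr_fit <- function(object, ...) {
  d <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s * 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fluorescence)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "Time (us)", y = "Fluorescence (rel.)",
                  title = sprintf("sigma_PSII = %.0f A^2 quanta^-1, rho = %.2f",
                                  object$sigma_psii, object$rho))
}

#' Plot a pooled kinetic fit
#'
#' Observed versus fitted trajectories for each pooled course.
#'
#' @param object A `pooled_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pooled_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(.data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~sample_id, scales = "free") +
    ggplot2::labs(x = "t (s)", y = "Observed / fitted",
                  title = object$model)
}

#' Plot a band comparison
#'
#' Group-mean second derivatives across the compared window with the
#' significant wavelengths marked.
#'
#' @param object A `band_comparison` from [compare_band()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("mean_a", "mean_b"),
                              names_to = "group")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(as_tibble(object), .data$significant),
      mapping = ggplot2::aes(x = .data$wavelength_nm,
                             y = pmin(.data$mean_a, .data$mean_b)),
      inherit.aes = FALSE,
      shape = 8, colour = "black"
    ) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Normalised 2nd derivative",
                  colour = "Group")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
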