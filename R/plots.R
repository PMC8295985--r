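# ggplot2 graphics for the main result types.

#' Plot dispersion profiles
#'
#' R2eff against the effective CPMG field, one panel per peak, colored
#' by temperature and shaped by static field.
#'
#' @param data Dispersion dataset (optionally with a `.fitted` column,
#'   drawn as lines).
#' @return A ggplot object.
#' @export
plot_dispersion <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$nu_cpmg_Hz, y = .data$r2eff,
    colour = factor(.data$temperature_C),
    shape = factor(.data$field_MHz))) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$peak_id), scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * eff] ~ (s^-1)),
                  colour = "T (°C)", shape = "field (MHz)") +
    ggplot2::theme_bw()
  if (".fitted" %in% names(data))
    p <- p + ggplot2::geom_line(ggplot2::aes(
      y = .data$.fitted,
      group = interaction(.data$temperature_C, .data$field_MHz)),
      linewidth = 0.4)
  p
}

#' Autoplot a global dispersion fit
#'
#' Dispersion profiles with the fitted Carver-Richards curves overlaid.
#'
#' @param object An `rd_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rd_fit <- function(object, ...) {
  plot_dispersion(object$data)
}

#' Autoplot an RDC tensor fit
#'
#' Observed against back-calculated couplings with the identity line.
#'
#' @param object An `rdc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdc_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions, ggplot2::aes(
    x = .data$D_calc_Hz, y = .data$D_obs_Hz)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "back-calculated D (Hz)", y = "observed D (Hz)",
      subtitle = sprintf("R-factor = %.1f%%", 100 * object$r_factor)) +
    ggplot2::theme_bw()
}

#' Plot a thermal melt with its derivative
#'
#' @param curve Melt curve (`temperature_C`, `theta_222`).
#' @return A ggplot object with the extracted Tm marked.
#' @export
plot_melt <- function(curve) {
  tm <- extract_tm(curve)
  ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$temperature_C, y = .data$theta_222)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = tm$tm_C, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "temperature (°C)",
                  y = expression(theta[222] ~ "(mdeg)"),
                  subtitle = sprintf("Tm = %.1f °C", tm$tm_C)) +
    ggplot2::theme_bw()
}
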