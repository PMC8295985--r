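# Physical constants and nucleus frequency helpers shared across the package.

#' Physical constants used throughout cpmgfit
#'
#' CODATA values for the Boltzmann constant (J K-1), the Planck constant
#' (J s) and the molar gas constant (J mol-1 K-1), plus the gyromagnetic
#' ratios of 15N and 13C expressed as fractions of the 1H ratio. The
#' gamma ratios convert a spectrometer's nominal 1H frequency (MHz) into
#' the resonance frequency of the heteronucleus.
#'
#' @format A named list with elements `kB`, `h`, `R`, `gamma_ratio`
#'   (named vector with entries `15N` and `13C`) and `celsius_offset`.
#' @export
nmr_constants <- list(
  kB = 1.380649e-23,
  h  = 6.62607015e-34,
  R  = 8.31446,
  gamma_ratio = c("15N" = 0.10136767, "13C" = 0.25145002),
  celsius_offset = 273.15
)

#' Convert Celsius to Kelvin
#'
#' @param temperature_C Temperature(s) in degrees Celsius.
#' @return Temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) {
  temperature_C + nmr_constants$celsius_offset
}

#' Heteronucleus resonance frequency
#'
#' Resonance frequency of a 15N or 13C nucleus on a spectrometer of the
#' given nominal 1H frequency.
#'
#' @param field_MHz Spectrometer 1H frequency in MHz (e.g. 600, 800).
#' @param nucleus `"15N"` or `"13C"`.
#' @return Frequency in Hz.
#' @export
#' @examples
#' nucleus_frequency_hz(800, "15N") # ~81.1 MHz
nucleus_frequency_hz <- function(field_MHz, nucleus = c("15N", "13C")) {
  nucleus <- match.arg(nucleus, names(nmr_constants$gamma_ratio),
                       several.ok = TRUE)
  field_MHz * 1e6 * unname(nmr_constants$gamma_ratio[nucleus])
}

#' Convert a chemical-shift difference from ppm to rad/s
#'
#' @param dw_ppm Shift difference in ppm.
#' @inheritParams nucleus_frequency_hz
#' @return Angular frequency difference in rad/s.
#' @export
ppm_to_rad_s <- function(dw_ppm, field_MHz, nucleus = c("15N", "13C")) {
  dw_ppm * 1e-6 * 2 * pi * nucleus_frequency_hz(field_MHz, nucleus)
}

# internal: consistent stop() with a class so tests can assert on it
abort_input <- function(msg) {
  stop(structure(class = c("cpmgfit_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
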