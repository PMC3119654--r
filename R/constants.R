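# Physical constants and unit helpers used throughout the package.
#
# Unit conventions (package-wide):
#   voltage mV, current pA (outward positive), conductance nS, time ms for
#   electrophysiology and s for cell-scale simulations, concentration mM,
#   volume L, temperature degrees Celsius, pH dimensionless.

#' Physical constants
#'
#' Faraday constant (C mol^-1) and molar gas constant (J K^-1 mol^-1) as
#' used by every equilibrium-potential and flux calculation in the package.
#'
#' @format Named numeric values.
#' @name constants
#' @keywords internal
NULL

FARADAY <- 96485.33212
GAS_CONSTANT <- 8.31446262

#' Nernst slope at a given temperature
#'
#' Returns the slope of the Nernst relation, `2.303 * R * T / F`, in mV per
#' tenfold concentration ratio (per pH unit for H+), for a monovalent ion.
#' At 20 degrees C this is 58.17 mV/decade.
#'
#' @param temperature_c Temperature in degrees Celsius.
#' @return Slope in mV per decade.
#' @examples
#' nernst_slope_mv(20) # 58.17
#' @export
nernst_slope_mv <- function(temperature_c) {
  stopifnot(is.numeric(temperature_c), temperature_c > -273.15)
  log(10) * GAS_CONSTANT * (temperature_c + 273.15) / FARADAY * 1000
}

#' RT/F in mV
#' @param temperature_c Temperature in degrees Celsius.
#' @return RT/F in mV.
#' @keywords internal
rt_over_f_mv <- function(temperature_c) {
  GAS_CONSTANT * (temperature_c + 273.15) / FARADAY * 1000
}

# internal: stop with a consistent domain-error class
domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("hvchan_domain_error", "error")))
}
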