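#' Physical constants and Nernst potentials
#'
#' Units used throughout the package: mV, ms, mM, cm, S/cm2, mA/cm2, uF/cm2.
#' With these units I (mA/cm2) = g (S/cm2) * (V - E) (mV) without conversion
#' factors, and concentration changes follow
#' d\[X\]/dt (mM/ms) = -I * area / (z * F * volume) with area in cm2 and
#' volume in cm3.
#'
#' @name units
NULL

#' Faraday constant, C/mol
#' @keywords internal
FARADAY <- 96485.332

#' Gas constant, J/(mol K)
#' @keywords internal
GAS_R <- 8.31446

#' Thermal voltage RT/F in mV
#'
#' @param temperature_c bath temperature in degrees Celsius.
#' @return RT/F in mV.
#' @export
#' @examples
#' rtf_mV(32)
rtf_mV <- function(temperature_c = 32) {
  1000 * GAS_R * (273.15 + temperature_c) / FARADAY
}

#' Nernst equilibrium potential
#'
#' @param x_out,x_in extracellular and intracellular concentrations (mM), > 0.
#' @param z ionic valence (signed integer; -1 for Cl- and HCO3-).
#' @param temperature_c bath temperature, degrees Celsius.
#' @return equilibrium potential in mV.
#' @export
#' @examples
#' nernst(140, 14, z = 1)  # ~ +61 mV ten-fold cation gradient at 32 C
nernst <- function(x_out, x_in, z, temperature_c = 32) {
  if (any(x_out <= 0) || any(x_in <= 0)) {
    stop("nernst(): concentrations must be positive", call. = FALSE)
  }
  rtf_mV(temperature_c) / z * log(x_out / x_in)
}

# Column order used for the per-compartment concentration matrix.
ION_COLS <- c("na_i", "k_i", "cl_i", "ca_i", "na_o", "k_o", "cl_o", "ca_o")
ION_NAMES <- c("na", "k", "cl", "ca")
ION_Z <- c(na = 1, k = 1, cl = -1, ca = 2)
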