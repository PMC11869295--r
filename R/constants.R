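## Physical constants shared across all modules. Energies are kcal/mol,
## distances Angstrom, potentials mV vs NHE unless stated otherwise.

.kB_kcal <- 0.0019872041     # Boltzmann constant, kcal mol^-1 K^-1
.F_kcal_per_V <- 23.061      # Faraday constant, kcal mol^-1 V^-1
.TST_PREFACTOR <- 6e12       # kB*T/h at physiological temperature, s^-1

#' Thermal energy
#'
#' `kBT()` returns the thermal energy in kcal/mol at the given temperature;
#' `kBT_eV()` returns the same quantity in electron volts. The default 310 K
#' gives 0.6160 kcal/mol (0.02671 eV), the single temperature used throughout
#' the surrogate simulations and rate conversions.
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy (scalar).
#' @examples
#' kBT()        # 0.616 kcal/mol
#' kBT_eV(310)  # 0.0267 eV
#' @export
kBT <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_kcal * temperature
}

#' @rdname kBT
#' @export
kBT_eV <- function(temperature = 310) {
  kBT(temperature) / .F_kcal_per_V
}
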