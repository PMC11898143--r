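#' Convert a gas mole fraction (ppm) to mass concentration
#'
#' Ideal-gas conversion between the volumetric mixing ratio reported by gas
#' sensors (parts per million by volume) and the mass concentration
#' (g m^-3) required by the tracer-gas emission balance.
#'
#' @param ppm Numeric vector of mixing ratios in ppm (by volume).
#' @param gas One of `"nh3"`, `"co2"`, `"h2s"`.
#' @param temp Air temperature in degrees Celsius (default 20).
#' @param pressure Barometric pressure in Pa (default 101325).
#'
#' @return Mass concentration in g m^-3, same length as `ppm`.
#'
#' @details
#' `g m^-3 = ppm * 1e-6 * M * P / (R * T)` with molar masses
#' M(NH3) = 17.031, M(CO2) = 44.01, M(H2S) = 34.08 g mol^-1 and
#' R = 8.314462618 J mol^-1 K^-1. At 20 degC and 101325 Pa, 1 ppm NH3 is
#' 7.08e-4 g m^-3 and 1 ppm CO2 is 1.829e-3 g m^-3.
#'
#' @examples
#' ppm_to_mass_conc(1, "nh3")          # ~7.08e-4 g m^-3
#' mass_conc_to_ppm(7.08e-4, "nh3")    # ~1 ppm
#' @export
ppm_to_mass_conc <- function(ppm, gas = c("nh3", "co2", "h2s"),
                             temp = 20, pressure = 101325) {
  gas <- match.arg(gas)
  if (any(temp <= -273.15)) stop_barnsense("temperature below absolute zero",
                                           "barnsense_domain_error")
  if (any(pressure <= 0)) stop_barnsense("pressure must be positive",
                                         "barnsense_domain_error")
  m <- MOLAR_MASS[[gas]]
  ppm * 1e-6 * m * pressure / (R_GAS * (temp + 273.15))
}

#' @rdname ppm_to_mass_conc
#' @param conc Mass concentration in g m^-3.
#' @export
mass_conc_to_ppm <- function(conc, gas = c("nh3", "co2", "h2s"),
                             temp = 20, pressure = 101325) {
  gas <- match.arg(gas)
  conc / ppm_to_mass_conc(1, gas, temp = temp, pressure = pressure)
}

R_GAS <- 8.314462618
MOLAR_MASS <- list(nh3 = 17.031, co2 = 44.01, h2s = 34.08)
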