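#' Isotope and gas constants
#'
#' `R_VPDB` is the 13C/12C ratio of the Vienna-Pee Dee Belemnite standard
#' used to convert between delta notation and isotopologue ratios.
#'
#' @format A length-1 numeric.
#' @export
R_VPDB <- 0.0111802

#' Molar volume of an ideal gas
#'
#' Molar volume in litres per mole at 1 atm and the given temperature,
#' used to convert between ppm changes in a chamber of known volume and
#' molar CO2 fluxes.
#'
#' @param temp_C temperature in degrees Celsius.
#' @return molar volume, l mol-1.
#' @export
molar_volume <- function(temp_C) {
  22.414 * (temp_C + 273.15) / 273.15
}

#' Convert delta13C to a 13C/12C ratio
#'
#' @param delta delta13C in per mil vs V-PDB.
#' @return isotope ratio R = 13C/12C.
#' @export
ratio_from_delta <- function(delta) {
  R_VPDB * (1 + delta / 1000)
}

#' Convert a 13C/12C ratio to delta13C
#'
#' @param ratio isotope ratio 13C/12C.
#' @return delta13C in per mil vs V-PDB.
#' @export
delta_from_ratio <- function(ratio) {
  (ratio / R_VPDB - 1) * 1000
}

# split a total amount (flux or concentration) into isotopologues at delta
split_isotopologues <- function(total, delta) {
  r <- ratio_from_delta(delta)
  light <- total / (1 + r)
  list(c12 = light, c13 = light * r)
}
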