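#' Energy unit conversion between kT and kcal/mol
#'
#' All internal energies in this package are expressed in units of kT
#' (thermal energy), i.e. beta = 1.  Experimental and simulation inputs are
#' often quoted in kcal/mol at a stated temperature; these helpers convert
#' between the two.  At 300 K, kT = 0.59616 kcal/mol.
#'
#' @param x energies to convert.
#' @param temperature temperature in Kelvin (default 300).
#' @return converted energies.
#' @examples
#' kcal_to_kt(10)          # a 10 kcal/mol umbrella force constant in kT
#' kt_to_kcal(kcal_to_kt(1))
#' @export
kcal_to_kt <- function(x, temperature = 300) {
  x / kt_in_kcal(temperature)
}

#' @rdname kcal_to_kt
#' @export
kt_to_kcal <- function(x, temperature = 300) {
  x * kt_in_kcal(temperature)
}

#' @rdname kcal_to_kt
#' @export
kt_in_kcal <- function(temperature = 300) {
  # Boltzmann constant in kcal/(mol K); 0.0019872 * 300 = 0.59616
  0.0019872 * temperature
}
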