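#' Unit constants used throughout the package
#'
#' Fixed conversion constants for the maritime unit dialects that appear in
#' vessel records and conversion equations: the metric tonne, the U.S.
#' customary ton (1016 kg, also called the long ton), the per-person and
#' per-luggage masses used to correct a light-ship (net) weight up to a
#' maximum displacement, and the knot.
#'
#' @return A named list with elements `tonne_kg` (1000), `us_ton_kg` (1016),
#'   `person_kg` (75), `luggage_kg` (20) and `knot_kmh` (1.852).
#' @examples
#' vm_units()$us_ton_kg
#' @export
vm_units <- function() {
  list(
    tonne_kg = 1000,
    us_ton_kg = 1016,
    person_kg = 75,
    luggage_kg = 20,
    knot_kmh = 1.852
  )
}

#' Convert a speed in knots to metres per second
#'
#' Uses 1 kn = 1.852 km/h, so 10 kn is 5.1444... m/s.
#'
#' @param speed_kn Numeric vector of speeds in knots.
#' @return Speeds in m/s.
#' @examples
#' knots_to_ms(10)
#' @export
knots_to_ms <- function(speed_kn) {
  stopifnot(is.numeric(speed_kn))
  speed_kn * vm_units()$knot_kmh / 3.6
}
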