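#' @title Pinned atomic mass and isotope abundance table
#' @description Monoisotopic masses (lightest isotope, u) and relative
#'   isotopic abundances by nominal mass offset from the lightest isotope,
#'   from the IUPAC/CIAAW 2021 compilation. Pinned here so that printed ion
#'   m/z values are reproducible to 4 decimal places independent of any
#'   external library version.
#' @keywords internal
#' @noRd
.ELEMENTS <- list(
  H  = list(mass = 1.00782503207,  abund = c(0.999885, 0.000115)),
  C  = list(mass = 12.0,           abund = c(0.9893, 0.0107)),
  N  = list(mass = 14.0030740048,  abund = c(0.99636, 0.00364)),
  O  = list(mass = 15.9949146196,  abund = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.9984031627,  abund = 1),
  Na = list(mass = 22.9897692809,  abund = 1),
  P  = list(mass = 30.9737619984,  abund = 1),
  S  = list(mass = 31.9720711744,  abund = c(0.9499, 0.0075, 0.0425, 0, 0.0001)),
  Cl = list(mass = 34.968852682,   abund = c(0.7576, 0, 0.2424)),
  K  = list(mass = 38.9637064864,  abund = c(0.932581, 0.000117, 0.067302)),
  Br = list(mass = 78.9183376,     abund = c(0.5069, 0, 0.4931)),
  I  = list(mass = 126.9044719,    abund = 1)
)

#' Physical constants of the ion mass scale
#'
#' `electron_mass` is the CODATA electron rest mass in u.
#' `deuterium_mass_step` is m(2H) - m(1H), the exact-mass shift produced by
#' one hydrogen-to-deuterium replacement; deuterated channel k of an ion sits
#' at `mz + k * deuterium_mass_step`. Rounded to 4 decimals this is the
#' 1.0063 search window centre used for ladder detection.
#'
#' @format Numeric scalars.
#' @examples
#' round(deuterium_mass_step, 4) # 1.0063
#' @export
electron_mass <- 0.000548579909

#' @rdname electron_mass
#' @export
deuterium_mass_step <- 2.01410177785 - 1.00782503207
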