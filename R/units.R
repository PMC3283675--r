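#' Convert between SI and conventional biophysics units
#'
#' All internal computation in rbclesion is SI; inputs and reports use the
#' units conventional in the red-cell literature (cP for viscosity, dyne/cm
#' for membrane elasticity, mV for zeta potential, um/s for drag velocities).
#' This helper performs the exact scale-factor conversions between the two.
#'
#' @param value Numeric vector to convert.
#' @param from,to Unit names. Supported pairs (either direction):
#'   `"cP"`/`"Pa.s"`, `"dyne/cm"`/`"N/m"`, `"mV"`/`"V"`, `"um/s"`/`"m/s"`,
#'   `"um"`/`"m"`. Converting a unit to itself is the identity.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_units(1.65, "cP", "Pa.s")      # 0.00165
#' convert_units(4.1e-4, "dyne/cm", "N/m") # 4.1e-7
#' convert_units(-14.5, "mV", "V")         # -0.0145
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), is.character(from), is.character(to),
            length(from) == 1L, length(to) == 1L)
  if (from == to) return(value)
  # scale of each unit relative to its SI partner
  si_scale <- c(
    "cP"      = 1e-3,  "Pa.s" = 1,
    "dyne/cm" = 1e-3,  "N/m"  = 1,
    "mV"      = 1e-3,  "V"    = 1,
    "um/s"    = 1e-6,  "m/s"  = 1,
    "um"      = 1e-6,  "m"    = 1
  )
  family <- c(
    "cP" = "viscosity", "Pa.s" = "viscosity",
    "dyne/cm" = "spring", "N/m" = "spring",
    "mV" = "potential", "V" = "potential",
    "um/s" = "velocity", "m/s" = "velocity",
    "um" = "length", "m" = "length"
  )
  if (!from %in% names(si_scale) || !to %in% names(si_scale) ||
      family[[from]] != family[[to]]) {
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  }
  value * si_scale[[from]] / si_scale[[to]]
}
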