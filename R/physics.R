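#' Suspension medium constants
#'
#' The electrokinetic and hydrodynamic computations need two properties of the
#' suspending serum: its electrical permittivity and its dynamic viscosity.
#' Defaults are the measured values for AB blood serum used throughout the
#' package: permittivity 1.06e-9 C^2 N^-1 m^-2 and viscosity 1.65 cP
#' (Ostwald viscometry), i.e. 1.65e-3 Pa s.
#'
#' @param permittivity Electrical permittivity, C^2 N^-1 m^-2.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return A list of class `"rbl_medium"` with fields `permittivity` and
#'   `viscosity`.
#' @examples
#' medium()
#' medium(viscosity = convert_units(1.2, "cP", "Pa.s"))
#' @export
medium <- function(permittivity = 1.06e-9, viscosity = 1.65e-3) {
  stopifnot(is.numeric(permittivity), length(permittivity) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L)
  if (!is.finite(permittivity) || permittivity <= 0)
    stop("permittivity must be strictly positive", call. = FALSE)
  if (!is.finite(viscosity) || viscosity <= 0)
    stop("viscosity must be strictly positive", call. = FALSE)
  structure(list(permittivity = permittivity, viscosity = viscosity),
            class = "rbl_medium")
}

#' Electrophoresis / drag chamber geometry
#'
#' Describes the measurement chamber: the electrode separation `d` that turns
#' an applied voltage into a field (E = V/d), and the distances from the
#' trapped cell to the bottom wall (`z_bottom`, measured by refocusing the
#' chamber floor, 50 um in the reference protocol) and to the cover slip
#' (`z_top`). The drag force on a cell moving between two parallel walls
#' scales with the harmonic combination 1/z_eq = 1/z_bottom + 1/z_top,
#' computed here once and stored.
#'
#' @param electrode_separation Electrode distance d, m.
#' @param z_bottom,z_top Distances to the chamber floor and cover slip, m.
#' @return A list of class `"rbl_chamber"` with fields `electrode_separation`,
#'   `z_bottom`, `z_top` and the derived `z_eq`.
#' @examples
#' chamber()                       # d = 1 cm, z1 = z2 = 50 um, z_eq = 25 um
#' chamber(z_top = 30e-6)$z_eq     # 18.75 um
#' @export
chamber <- function(electrode_separation = 1e-2,
                    z_bottom = 50e-6, z_top = 50e-6) {
  for (v in c(electrode_separation, z_bottom, z_top)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("chamber dimensions must be strictly positive finite numbers",
           call. = FALSE)
  }
  structure(list(electrode_separation = electrode_separation,
                 z_bottom = z_bottom, z_top = z_top,
                 z_eq = z_equivalent(z_bottom, z_top)),
            class = "rbl_chamber")
}

#' Cell geometry for the drag force balance
#'
#' The drag/elastic force balance needs the cell's rest length L0 (its length
#' with no force applied) and the effective drag-bearing area. Under the
#' default disk convention the area is that of a disk of diameter L0,
#' `pi * (rest_length / 2)^2`; a custom area can be supplied to explore other
#' shape conventions.
#'
#' @param rest_length Rest length L0, m (a fresh discocyte is ~8 um across).
#' @param effective_area Drag-bearing area, m^2; default the L0 disk.
#' @return A list of class `"rbl_geometry"` with fields `rest_length` and
#'   `effective_area`.
#' @examples
#' cell_geometry(8e-6)$effective_area  # 5.027e-11 m^2
#' @export
cell_geometry <- function(rest_length = 8e-6,
                          effective_area = pi * (rest_length / 2)^2) {
  if (!is.numeric(rest_length) || length(rest_length) != 1L ||
      !is.finite(rest_length) || rest_length <= 0)
    stop("rest_length must be strictly positive", call. = FALSE)
  if (!is.numeric(effective_area) || length(effective_area) != 1L ||
      !is.finite(effective_area) || effective_area <= 0)
    stop("effective_area must be strictly positive", call. = FALSE)
  structure(list(rest_length = rest_length, effective_area = effective_area),
            class = "rbl_geometry")
}

#' Electric field from applied voltage
#'
#' E = V/d for a parallel-electrode chamber with separation d.
#'
#' @param voltage Applied potential, V (vectorised).
#' @param chamber An [chamber()] object (or its electrode separation, m).
#' @return Field magnitude, V m^-1.
#' @examples
#' field_from_voltage(50, chamber())  # 5000 V/m
#' @export
field_from_voltage <- function(voltage, chamber = rbclesion::chamber()) {
  d <- if (inherits(chamber, "rbl_chamber")) chamber$electrode_separation
       else chamber
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("invalid geometry: electrode separation must be > 0", call. = FALSE)
  stopifnot(is.numeric(voltage), all(is.finite(voltage)), all(voltage >= 0))
  voltage / d
}

#' Smoluchowski inversion: zeta potential from electrophoretic mobility
#'
#' In the thin-double-layer (Smoluchowski) regime the electrophoretic mobility
#' of a suspended cell — the slope of its terminal velocity against the field
#' — determines the zeta potential as `zeta = viscosity * mobility /
#' permittivity`. The mobility's sign encodes the charge polarity (red cells
#' are negative), and the map is linear, so the inversion is exact.
#'
#' @param mobility Electrophoretic mobility, m^2 V^-1 s^-1 (vectorised; may be
#'   negative).
#' @param medium A [medium()] object.
#' @return Zeta potential, V.
#' @examples
#' convert_units(zeta_from_mobility(-9.314e-9, medium()), "V", "mV") # -14.5 mV
#' @export
zeta_from_mobility <- function(mobility, medium = rbclesion::medium()) {
  stopifnot(inherits(medium, "rbl_medium"), is.numeric(mobility))
  if (any(!is.finite(mobility)))
    stop("mobility must be finite", call. = FALSE)
  medium$viscosity * mobility / medium$permittivity
}

#' Forward Smoluchowski map: mobility from zeta potential
#'
#' Exact inverse of [zeta_from_mobility()]: `mobility = permittivity * zeta /
#' viscosity`. Used as the forward model by the sweep simulator — a cell of
#' zeta potential zeta in field E migrates at terminal velocity
#' `mobility * E`.
#'
#' @param zeta Zeta potential, V (vectorised).
#' @inheritParams zeta_from_mobility
#' @return Mobility, m^2 V^-1 s^-1.
#' @export
mobility_from_zeta <- function(zeta, medium = rbclesion::medium()) {
  stopifnot(inherits(medium, "rbl_medium"), is.numeric(zeta))
  if (any(!is.finite(zeta)))
    stop("zeta must be finite", call. = FALSE)
  medium$permittivity * zeta / medium$viscosity
}

#' Equivalent wall distance between two parallel surfaces
#'
#' A cell dragged at depth Z1 above the chamber floor and Z2 below the cover
#' slip feels shear against both walls; the combined drag scales as
#' 1/z_eq = 1/z_bottom + 1/z_top. Symmetric in its arguments and always
#' smaller than either distance.
#'
#' @param z_bottom,z_top Wall distances, m (vectorised).
#' @return Equivalent distance z_eq, m.
#' @examples
#' z_equivalent(50e-6, 50e-6)  # 25 um
#' @export
z_equivalent <- function(z_bottom, z_top) {
  stopifnot(is.numeric(z_bottom), is.numeric(z_top))
  if (any(!is.finite(z_bottom)) || any(!is.finite(z_top)) ||
      any(z_bottom <= 0) || any(z_top <= 0))
    stop("invalid geometry: wall distances must be strictly positive",
         call. = FALSE)
  1 / (1 / z_bottom + 1 / z_top)
}

#' Wall-corrected viscous drag force on a dragged cell
#'
#' Shear-stress model for a cell dragged at speed v between two walls:
#' `force = viscosity * velocity * effective_area / z_eq`. The velocity
#' gradient between cell surface and each wall contributes stress
#' viscosity*v/Z over the drag-bearing area, and the two walls combine through
#' the harmonic z_eq. Linear in velocity and viscosity.
#'
#' @param medium A [medium()] object.
#' @param velocity Drag speed, m s^-1, >= 0 (vectorised).
#' @param geometry A [cell_geometry()] object.
#' @param z_eq Equivalent wall distance, m (see [z_equivalent()]).
#' @return Drag force, N.
#' @examples
#' drag_force(medium(), 200e-6, cell_geometry(8e-6), 25e-6)  # ~6.6e-13 N
#' @export
drag_force <- function(medium, velocity, geometry, z_eq) {
  stopifnot(inherits(medium, "rbl_medium"), inherits(geometry, "rbl_geometry"),
            is.numeric(velocity))
  if (!is.numeric(z_eq) || length(z_eq) != 1L || !is.finite(z_eq) || z_eq <= 0)
    stop("invalid geometry: z_eq must be > 0", call. = FALSE)
  if (any(!is.finite(velocity)) || any(velocity < 0))
    stop("velocity must be finite and non-negative", call. = FALSE)
  medium$viscosity * velocity * geometry$effective_area / z_eq
}

#' Equilibrium elongation of a dragged cell
#'
#' At terminal drag the elastic restoring force mu * delta_L balances the
#' viscous drag, so the equilibrium deformation is
#' `delta_L = drag_force / mu`, with mu the cell's apparent elasticity (an
#' effective whole-cell spring constant, N m^-1; stiffer cells deform less).
#' This is the forward model the elongation-sweep simulator uses.
#'
#' @param mu Apparent elasticity, N m^-1, > 0.
#' @inheritParams drag_force
#' @return Deformation delta_L = L - L0, m.
#' @examples
#' mu <- convert_units(4.1e-4, "dyne/cm", "N/m")
#' deformation_from_velocity(mu, medium(), 200e-6, cell_geometry(8e-6), 25e-6)
#' @export
deformation_from_velocity <- function(mu, medium, velocity, geometry, z_eq) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("invalid parameter: mu must be > 0", call. = FALSE)
  drag_force(medium, velocity, geometry, z_eq) / mu
}
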