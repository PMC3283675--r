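#' Per-cell zeta potential from voltage sweeps
#'
#' For each cell, the sweep records the terminal migration velocity at a
#' series of applied voltages (the reference protocol uses 30, 40, 50, 60, 70
#' and 80 V on the same cell, recapturing it with the tweezers between
#' steps). Voltages are converted to fields (E = V/d), the speed is fitted
#' proportional to the field ([fit_proportional()]; physics forces v = 0 at
#' E = 0), and the slope — the electrophoretic mobility — is mapped to zeta
#' through the Smoluchowski relation ([zeta_from_mobility()]). The mobility
#' magnitude is fitted; the sign is taken from the observed migration
#' direction, so a negative cell drifting toward the anode yields negative
#' zeta.
#'
#' @param sweeps Data frame with columns `cell_id`, `voltage_V`,
#'   `velocity_m_s` (signed); any additional columns constant within a cell
#'   (e.g. `day`, `arm`) are carried through.
#' @param chamber A [chamber()] object.
#' @param medium A [medium()] object.
#' @return Tibble, one row per cell: carried metadata, `mobility_m2_Vs`,
#'   `zeta_V`, `zeta_mV`, `pearson_r` (of speed vs field), `n_points`.
#' @examples
#' sw <- tibble::tibble(cell_id = "c1", voltage_V = seq(30, 80, 10),
#'                      velocity_m_s = -9.314e-9 * seq(30, 80, 10) / 1e-2)
#' estimate_zeta(sw)
#' @export
estimate_zeta <- function(sweeps, chamber = rbclesion::chamber(),
                          medium = rbclesion::medium()) {
  check_sweep_frame(sweeps, c("cell_id", "voltage_V", "velocity_m_s"))
  meta <- carried_metadata(sweeps, c("voltage_V", "velocity_m_s"))
  est <- sweeps |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3L)
        stop("insufficient data: cell ", key$cell_id,
             " has fewer than 3 sweep points", call. = FALSE)
      if (any(df$voltage_V <= 0) || anyNA(df$voltage_V))
        stop("voltages must be positive", call. = FALSE)
      E <- field_from_voltage(df$voltage_V, chamber)
      v <- df$velocity_m_s
      direction <- sign(sum(sign(v)))
      fit <- fit_proportional(E, abs(v))
      mobility <- direction * fit$slope
      zeta <- zeta_from_mobility(mobility, medium)
      tibble::tibble(mobility_m2_Vs = mobility, zeta_V = zeta,
                     zeta_mV = convert_units(zeta, "V", "mV"),
                     pearson_r = fit$pearson_r, n_points = fit$n)
    }) |>
    dplyr::ungroup()
  if (ncol(meta) > 1L) est <- dplyr::left_join(meta, est, by = "cell_id")
  tibble::as_tibble(est)
}

#' Per-cell apparent elasticity from elongation sweeps
#'
#' For each cell, the sweep records the steady-state cell length at a series
#' of constant drag velocities (140-290 um/s in the reference protocol). The
#' deformation delta_L = L - L0 is fitted proportional to the velocity, and
#' the force balance mu * delta_L = viscosity * v * A_eff / z_eq gives the
#' apparent elasticity `mu = viscosity * A_eff / (z_eq * slope)`. Larger mu
#' means a stiffer, less deformable cell.
#'
#' @param sweeps Data frame with columns `cell_id`, `velocity_m_s` (drag
#'   speed, positive), `length_m`, and `rest_length_m` (L0, constant within a
#'   cell); extra constant columns are carried through.
#' @param chamber A [chamber()] object (its `z_eq` is used).
#' @param medium A [medium()] object.
#' @param area_model How the drag-bearing area follows from L0; currently
#'   `"disk"` (area of a disk of diameter L0).
#' @return Tibble, one row per cell: carried metadata, `slope_s` (d delta_L /
#'   d v), `mu_N_m`, `mu_dyne_cm`, `pearson_r`, `n_points`.
#' @export
estimate_elasticity <- function(sweeps, chamber = rbclesion::chamber(),
                                medium = rbclesion::medium(),
                                area_model = "disk") {
  check_sweep_frame(sweeps,
                    c("cell_id", "velocity_m_s", "length_m", "rest_length_m"))
  area_model <- match.arg(area_model)
  meta <- carried_metadata(sweeps, c("velocity_m_s", "length_m"))
  est <- sweeps |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3L)
        stop("insufficient data: cell ", key$cell_id,
             " has fewer than 3 sweep points", call. = FALSE)
      L0 <- df$rest_length_m[1L]
      geom <- cell_geometry(L0)
      dL <- df$length_m - L0
      fit <- fit_proportional(df$velocity_m_s, dL)
      if (fit$slope <= 0)
        stop("non-physical elasticity: cell ", key$cell_id,
             " shows no elongation with drag (slope <= 0)", call. = FALSE)
      mu <- medium$viscosity * geom$effective_area / (chamber$z_eq * fit$slope)
      tibble::tibble(slope_s = fit$slope, mu_N_m = mu,
                     mu_dyne_cm = convert_units(mu, "N/m", "dyne/cm"),
                     pearson_r = fit$pearson_r, n_points = fit$n)
    }) |>
    dplyr::ungroup()
  if (ncol(meta) > 1L) est <- dplyr::left_join(meta, est, by = "cell_id")
  tibble::as_tibble(est)
}

# shared input checks for the per-cell estimators
check_sweep_frame <- function(sweeps, required) {
  if (!is.data.frame(sweeps))
    stop("sweeps must be a data frame", call. = FALSE)
  missing <- setdiff(required, names(sweeps))
  if (length(missing))
    stop("sweeps is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- setdiff(required, "cell_id")
  for (col in num) {
    if (!is.numeric(sweeps[[col]]) || anyNA(sweeps[[col]]))
      stop("column ", col, " must be numeric with no missing values",
           call. = FALSE)
  }
  invisible(sweeps)
}

# columns constant within every cell (day, arm, donor, ...) carried to output
carried_metadata <- function(sweeps, measurement_cols) {
  cand <- setdiff(names(sweeps), measurement_cols)
  meta <- sweeps |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(setdiff(cand, "cell_id")),
      ~ if (dplyr::n_distinct(.x) == 1L) .x[1L] else NA
    ), .groups = "drop")
  keep <- vapply(meta, function(x) !all(is.na(x)), logical(1L))
  meta[, keep, drop = FALSE]
}
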