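#' Storage-time parameter schedule
#'
#' The generator draws each cell's true parameters from storage-day-dependent
#' distributions. The default standard-arm schedule is calibrated to the
#' published cohort: day means of zeta potential (mV) with their standard
#' errors at n = 40 cells/week, apparent elasticity (dyne/cm) with standard
#' errors at n = 20 cells/week (elasticity measurements begin on day 8; the
#' day-15 mean interpolates the 4.1-4.6 plateau, across which no significant
#' change was found), and the fraction of ROS-positive cells, which rises by
#' a factor 1.60 over the first week and a further 1.16 by day 36.
#' Between-cell standard deviations are reconstructed as `SE * sqrt(n)`.
#'
#' The leukodepleted arm covers days 1-15 at n = 20 (zeta only); its zeta
#' decay mirrors the standard arm, the observation that motivated ruling out
#' leukocyte enzymes as the cause of the decay.
#'
#' @param arm `"standard"` or `"leukodepleted"`.
#' @param ros_day1_frac Absolute ROS percent-positive fraction on day 1
#'   (not published; default 0.20). Ratios between days are insensitive to it.
#' @return Tibble with one row per storage day: `day`, `zeta_mean_mV`,
#'   `zeta_se_mV`, `zeta_sd_mV`, `mu_mean_dyne_cm`, `mu_se_dyne_cm`,
#'   `mu_sd_dyne_cm`, `ros_positive_frac` (elasticity and ROS columns are NA
#'   for the leukodepleted arm, where only zeta was followed).
#' @examples
#' storage_schedule()
#' @export
storage_schedule <- function(arm = c("standard", "leukodepleted"),
                             ros_day1_frac = 0.20) {
  arm <- match.arg(arm)
  stopifnot(ros_day1_frac > 0, ros_day1_frac <= 1)
  if (arm == "standard") {
    days <- c(1L, 8L, 15L, 22L, 29L, 36L)
    zeta_mean <- c(-14.5, -9.7, -10.3, -10.2, -8.5, -8.5)
    zeta_se <- c(0.7, 0.3, 0.3, 0.4, 0.4, 0.4)
    zeta_n <- 40
    mu_mean <- c(NA, 4.1e-4, 4.35e-4, 4.6e-4, 6.4e-4, 9.6e-4)
    mu_se <- c(NA, 0.6e-4, 0.55e-4, 0.5e-4, 1.0e-4, 1.0e-4)
    mu_n <- 20
    # multiplicative rise: x1.60 day 1 -> 8, then linearly to x1.16 by day 36
    p1 <- ros_day1_frac
    p8 <- 1.60 * p1
    p36 <- 1.16 * p8
    ros <- c(p1, stats::approx(c(8, 36), c(p8, p36), xout = days[-1L])$y)
  } else {
    days <- c(1L, 8L, 15L)
    zeta_mean <- c(-14.0, -9.5, -10.0)
    zeta_se <- c(0.5, 0.6, 0.4)
    zeta_n <- 20
    mu_mean <- mu_se <- rep(NA_real_, 3L)
    mu_n <- NA
    ros <- rep(NA_real_, 3L)
  }
  tibble::tibble(
    day = days, arm = arm,
    zeta_mean_mV = zeta_mean, zeta_se_mV = zeta_se,
    zeta_sd_mV = zeta_se * sqrt(zeta_n),
    mu_mean_dyne_cm = mu_mean, mu_se_dyne_cm = mu_se,
    mu_sd_dyne_cm = mu_se * sqrt(mu_n),
    ros_positive_frac = ros
  )
}

#' Cohort design
#'
#' How many cells are measured per storage day, mirroring the published
#' protocol: zeta sweeps on at least 40 cells (from 4 donors) each week over
#' 36 days of storage; elasticity sweeps on at least 20 cells each week from
#' day 8; the leukodepleted arm followed for 15 days at 20 cells/week.
#'
#' @param days Storage days measured (strictly increasing).
#' @param n_cells_zeta,n_cells_elastic Cells per day for each assay (>= 2).
#' @param arm Cohort arm label.
#' @param n_donors Donors per week (labels only).
#' @return A list of class `"rbl_design"`.
#' @export
cohort_design <- function(days = c(1L, 8L, 15L, 22L, 29L, 36L),
                          n_cells_zeta = 40L, n_cells_elastic = 20L,
                          arm = c("standard", "leukodepleted"),
                          n_donors = 4L) {
  arm <- match.arg(arm)
  if (arm == "leukodepleted" && missing(days)) days <- c(1L, 8L, 15L)
  if (arm == "leukodepleted" && missing(n_cells_zeta)) n_cells_zeta <- 20L
  stopifnot(length(days) >= 1L, !is.unsorted(days, strictly = TRUE),
            n_cells_zeta >= 2L, n_cells_elastic >= 2L, n_donors >= 1L)
  structure(list(days = as.integer(days),
                 n_cells_zeta = as.integer(n_cells_zeta),
                 n_cells_elastic = as.integer(n_cells_elastic),
                 arm = arm, n_donors = as.integer(n_donors)),
            class = "rbl_design")
}

#' Measurement noise model
#'
#' Noise injected by the synthetic measurement process: a multiplicative
#' relative error on recorded terminal velocities (default 4%, the level at
#' which per-cell velocity-field fits reproduce the observed regime of
#' correlation coefficients better than 0.98), Gaussian position noise on
#' video tracks, and Gaussian noise on segmented cell lengths.
#'
#' @param velocity_rel_sd Relative SD of recorded velocities (unitless).
#' @param position_noise_sd_m Track position noise SD, m (default 0.2 um).
#' @param length_noise_sd_m Cell-length noise SD, m (default 0.15 um).
#' @return A list of class `"rbl_noise"`.
#' @export
noise_model <- function(velocity_rel_sd = 0.04,
                        position_noise_sd_m = 0.2e-6,
                        length_noise_sd_m = 0.15e-6) {
  stopifnot(velocity_rel_sd >= 0, position_noise_sd_m >= 0,
            length_noise_sd_m >= 0)
  structure(list(velocity_rel_sd = velocity_rel_sd,
                 position_noise_sd_m = position_noise_sd_m,
                 length_noise_sd_m = length_noise_sd_m),
            class = "rbl_noise")
}

# Deterministic per-cell/per-stage substream seed below 2^31, so any cell's
# measurements can be regenerated without replaying the whole cohort.
substream_seed <- function(root_seed, index, stage) {
  (as.double(root_seed) * 48271 + index * 7919 + stage * 104729) %%
    2147483587 + 1
}

#' Draw a cohort of cells with storage-day-dependent true parameters
#'
#' Per-day truths: zeta ~ Normal(day mean, between-cell SD); elasticity mu ~
#' Normal truncated at zero; rest length L0 ~ Normal(8 um, 0.5 um) truncated
#' positive. Cells are tagged `assay = "zeta"` or `"elasticity"` (separate
#' cells per assay, as in the protocol); elasticity cells exist only for days
#' with a scheduled elasticity mean. Ground truth is returned in this table
#' and deliberately kept out of the simulated measurement tables.
#'
#' @param design A [cohort_design()].
#' @param schedule A [storage_schedule()] tibble (must cover every design
#'   day).
#' @param seed Root integer seed; the cohort is reproducible given it.
#' @return Tibble, one row per cell: `cell_id`, `day`, `arm`, `donor`,
#'   `assay`, `zeta_true_mV`, `mu_true_dyne_cm` (NA for zeta-assay cells),
#'   `L0_m`.
#' @examples
#' truth <- draw_cohort(cohort_design(n_cells_zeta = 4, n_cells_elastic = 2),
#'                      storage_schedule(), seed = 1)
#' @export
draw_cohort <- function(design, schedule = storage_schedule(design$arm),
                        seed = 1L) {
  stopifnot(inherits(design, "rbl_design"), is.data.frame(schedule))
  missing_days <- setdiff(design$days, schedule$day)
  if (length(missing_days))
    stop("schedule error: no schedule entry for day(s) ",
         paste(missing_days, collapse = ", "), call. = FALSE)
  sched <- schedule[match(design$days, schedule$day), ]
  rows <- purrr::map2(seq_along(design$days), design$days, function(i, d) {
    set.seed(substream_seed(seed, i, stage = 0L))
    sz <- design$n_cells_zeta
    zeta <- stats::rnorm(sz, sched$zeta_mean_mV[i], sched$zeta_sd_mV[i])
    out_z <- tibble::tibble(
      cell_id = sprintf("d%02d_z%03d", d, seq_len(sz)),
      day = d, arm = design$arm,
      donor = sprintf("donor%d", 1L + (seq_len(sz) - 1L) %% design$n_donors),
      assay = "zeta",
      zeta_true_mV = zeta, mu_true_dyne_cm = NA_real_,
      L0_m = truncated_normal(sz, 8e-6, 0.5e-6)
    )
    if (is.finite(sched$mu_mean_dyne_cm[i])) {
      se <- design$n_cells_elastic
      out_e <- tibble::tibble(
        cell_id = sprintf("d%02d_e%03d", d, seq_len(se)),
        day = d, arm = design$arm,
        donor = sprintf("donor%d", 1L + (seq_len(se) - 1L) %% design$n_donors),
        assay = "elasticity",
        zeta_true_mV = NA_real_,
        mu_true_dyne_cm = truncated_normal(se, sched$mu_mean_dyne_cm[i],
                                           sched$mu_sd_dyne_cm[i]),
        L0_m = truncated_normal(se, 8e-6, 0.5e-6)
      )
      out_z <- dplyr::bind_rows(out_z, out_e)
    }
    out_z
  })
  dplyr::bind_rows(rows)
}

# rejection-sampled Normal truncated at zero (physical positivity)
truncated_normal <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Simulate voltage sweeps for a cohort's zeta-assay cells
#'
#' For each cell and each voltage in the protocol, the true terminal
#' velocity is `mobility_from_zeta(zeta) * E` (signed; negative cells drift
#' against the field direction) and the recorded velocity carries a
#' multiplicative error `(1 + e)`, `e ~ Normal(0, velocity_rel_sd)`. Each
#' cell has its own deterministic noise substream, so two cells under the
#' same root seed receive independent draws and any subset of the cohort can
#' be regenerated identically.
#'
#' @param cohort Truth tibble from [draw_cohort()] (rows with
#'   `assay == "zeta"` are used).
#' @param chamber,medium Instrument models ([chamber()], [medium()]).
#' @param noise A [noise_model()].
#' @param voltages Applied voltages, V.
#' @param seed Root seed.
#' @return Tibble of measurements only (no truth columns): `cell_id`, `day`,
#'   `arm`, `voltage_V`, `velocity_m_s`.
#' @export
simulate_zeta_sweeps <- function(cohort, chamber = rbclesion::chamber(),
                                 medium = rbclesion::medium(),
                                 noise = noise_model(),
                                 voltages = seq(30, 80, by = 10),
                                 seed = 1L) {
  stopifnot(is.data.frame(cohort), inherits(noise, "rbl_noise"))
  cells <- dplyr::filter(cohort, .data$assay == "zeta")
  purrr::pmap_dfr(
    list(seq_len(nrow(cells)), cells$cell_id, cells$day, cells$arm,
         cells$zeta_true_mV),
    function(i, id, day, arm, zeta_mV) {
      set.seed(substream_seed(seed, i, stage = 1L))
      E <- field_from_voltage(voltages, chamber)
      v_true <- mobility_from_zeta(convert_units(zeta_mV, "mV", "V"),
                                   medium) * E
      v_obs <- v_true * (1 + stats::rnorm(length(E), 0, noise$velocity_rel_sd))
      tibble::tibble(cell_id = id, day = day, arm = arm,
                     voltage_V = voltages, velocity_m_s = v_obs)
    })
}

#' Simulate elongation sweeps for a cohort's elasticity-assay cells
#'
#' For each cell and each drag velocity (140-290 um/s protocol), the
#' steady-state length is `L0 + deformation_from_velocity(mu, v)` plus
#' Gaussian length noise. The effective drag area uses the cell's own L0
#' under the disk convention.
#'
#' @inheritParams simulate_zeta_sweeps
#' @param velocities Drag speeds, m/s (default six steps 140-290 um/s).
#' @return Tibble: `cell_id`, `day`, `arm`, `velocity_m_s`, `length_m`,
#'   `rest_length_m`.
#' @export
simulate_elongation_sweeps <- function(cohort,
                                       chamber = rbclesion::chamber(),
                                       medium = rbclesion::medium(),
                                       noise = noise_model(),
                                       velocities = seq(140e-6, 290e-6,
                                                        length.out = 6),
                                       seed = 1L) {
  stopifnot(is.data.frame(cohort), inherits(noise, "rbl_noise"))
  cells <- dplyr::filter(cohort, .data$assay == "elasticity")
  purrr::pmap_dfr(
    list(seq_len(nrow(cells)), cells$cell_id, cells$day, cells$arm,
         cells$mu_true_dyne_cm, cells$L0_m),
    function(i, id, day, arm, mu_dyne_cm, L0) {
      set.seed(substream_seed(seed, i, stage = 2L))
      mu <- convert_units(mu_dyne_cm, "dyne/cm", "N/m")
      geom <- cell_geometry(L0)
      dL <- deformation_from_velocity(mu, medium, velocities, geom,
                                      chamber$z_eq)
      L <- L0 + dL + stats::rnorm(length(velocities), 0,
                                  noise$length_noise_sd_m)
      tibble::tibble(cell_id = id, day = day, arm = arm,
                     velocity_m_s = velocities, length_m = L,
                     rest_length_m = L0)
    })
}

#' Simulate a tracked position-time series at constant velocity
#'
#' Emulates the video analysis input: a cell moving at constant terminal
#' velocity sampled at the camera frame rate, with Gaussian position noise.
#'
#' @param velocity_m_s True velocity (signed), m/s.
#' @param duration_s Track duration, s.
#' @param frame_rate_hz Camera frame rate, Hz (default 30).
#' @param position_noise_sd_m Position noise SD, m.
#' @param seed Integer seed.
#' @return Tibble with `t_s`, `x_m`, suitable for [terminal_velocity()].
#' @export
simulate_track <- function(velocity_m_s, duration_s = 1,
                           frame_rate_hz = 30,
                           position_noise_sd_m = 0.2e-6, seed = 1L) {
  stopifnot(duration_s > 0, frame_rate_hz > 0, position_noise_sd_m >= 0)
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / frame_rate_hz)
  tibble::tibble(
    t_s = t,
    x_m = velocity_m_s * t + stats::rnorm(length(t), 0, position_noise_sd_m)
  )
}

#' Simulate flow-cytometry-like ROS fluorescence events
#'
#' DCHF-DA fluoresces after oxidation, so the fraction of events above a
#' gating threshold scores ROS-positive cells. Intensities are drawn from a
#' two-component lognormal mixture: a dim ROS-negative population (meanlog
#' log 10, sdlog 0.4) and a bright positive one (meanlog log 100, sdlog 0.5).
#' Against the default threshold of 40 a.u. the negative population's
#' false-positive rate is ~0.03% and the positive population's sensitivity
#' ~97%, so observed percent-positive ratios between days track the
#' scheduled population fractions closely.
#'
#' @param day Storage day (must appear in `schedule` with a non-NA
#'   `ros_positive_frac`).
#' @param schedule A [storage_schedule()] tibble.
#' @param n_events Number of events (default 20000, the cytometer protocol).
#' @param seed Integer seed.
#' @param meanlog_neg,sdlog_neg,meanlog_pos,sdlog_pos Mixture components.
#' @return Tibble of class `"rbl_ros"`: `event_id`, `intensity`, plus
#'   attributes `day` and `threshold` (default gate, 40 a.u.).
#' @export
simulate_ros <- function(day, schedule = storage_schedule(),
                         n_events = 20000L, seed = 1L,
                         meanlog_neg = log(10), sdlog_neg = 0.4,
                         meanlog_pos = log(100), sdlog_pos = 0.5) {
  stopifnot(n_events >= 100L)
  i <- match(day, schedule$day)
  p <- if (is.na(i)) NA_real_ else schedule$ros_positive_frac[i]
  if (is.na(p) || p < 0 || p > 1)
    stop("schedule error: no valid ROS positive fraction for day ", day,
         call. = FALSE)
  set.seed(substream_seed(seed, day, stage = 3L))
  pos <- stats::runif(n_events) < p
  intensity <- ifelse(pos,
                      stats::rlnorm(n_events, meanlog_pos, sdlog_pos),
                      stats::rlnorm(n_events, meanlog_neg, sdlog_neg))
  out <- tibble::tibble(event_id = seq_len(n_events), intensity = intensity)
  attr(out, "day") <- day
  attr(out, "threshold") <- 40
  class(out) <- c("rbl_ros", class(out))
  out
}
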