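#' Default pipeline configuration
#'
#' A complete run configuration as a named list, serialisable to/from JSON.
#' Fields: `seed`, `arm`, `medium` (permittivity, viscosity_cP), `chamber`
#' (d_m, z1_m, z2_m), `cell` (L0_mean_m, L0_sd_m, area_model), `cohort`
#' (days, n_cells_zeta, n_cells_elastic), `noise` (velocity_rel_sd,
#' position_noise_sd_m, length_noise_sd_m), `ros` (n_events, threshold,
#' day1_positive_frac), `stages` (simulate, estimate, summarize).
#'
#' @param seed Root seed.
#' @param arm `"standard"` or `"leukodepleted"`.
#' @return Nested named list.
#' @export
default_config <- function(seed = 1L, arm = "standard") {
  design <- cohort_design(arm = arm)
  list(
    seed = as.integer(seed),
    arm = arm,
    medium = list(permittivity = 1.06e-9, viscosity_cP = 1.65),
    chamber = list(d_m = 1e-2, z1_m = 50e-6, z2_m = 50e-6),
    cell = list(L0_mean_m = 8e-6, L0_sd_m = 0.5e-6, area_model = "disk"),
    cohort = list(days = design$days,
                  n_cells_zeta = design$n_cells_zeta,
                  n_cells_elastic = design$n_cells_elastic),
    noise = list(velocity_rel_sd = 0.04,
                 position_noise_sd_m = 0.2e-6,
                 length_noise_sd_m = 0.15e-6),
    ros = list(n_events = 20000L, threshold = 40,
               day1_positive_frac = 0.20),
    stages = list(simulate = TRUE, estimate = TRUE, summarize = TRUE)
  )
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the published schema before any stage
#' runs: all required blocks and fields present, no unknown keys, values
#' positive where physics requires it.
#'
#' @param config Nested list (e.g. from [default_config()] or
#'   `jsonlite::read_json(..., simplifyVector = TRUE)`).
#' @return The config, invisibly, with integer-ish fields coerced; errors on
#'   any violation.
#' @export
validate_config <- function(config) {
  schema <- list(
    seed = NA, arm = NA,
    medium = c("permittivity", "viscosity_cP"),
    chamber = c("d_m", "z1_m", "z2_m"),
    cell = c("L0_mean_m", "L0_sd_m", "area_model"),
    cohort = c("days", "n_cells_zeta", "n_cells_elastic"),
    noise = c("velocity_rel_sd", "position_noise_sd_m", "length_noise_sd_m"),
    ros = c("n_events", "threshold", "day1_positive_frac"),
    stages = c("simulate", "estimate", "summarize")
  )
  cfg_err <- function(...) stop("config error: ", ..., call. = FALSE)
  if (!is.list(config)) cfg_err("configuration must be a list")
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) cfg_err("unknown key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(schema), names(config))
  if (length(missing)) cfg_err("missing block(s): ", paste(missing, collapse = ", "))
  for (blk in names(schema)) {
    fields <- schema[[blk]]
    if (length(fields) == 1L && is.na(fields[1L])) next
    unknown <- setdiff(names(config[[blk]]), fields)
    if (length(unknown))
      cfg_err("unknown key(s) in ", blk, ": ", paste(unknown, collapse = ", "))
    missing <- setdiff(fields, names(config[[blk]]))
    if (length(missing))
      cfg_err("missing field(s) in ", blk, ": ", paste(missing, collapse = ", "))
  }
  if (!config$arm %in% c("standard", "leukodepleted"))
    cfg_err("arm must be 'standard' or 'leukodepleted'")
  pos <- c(config$medium$permittivity, config$medium$viscosity_cP,
           config$chamber$d_m, config$chamber$z1_m, config$chamber$z2_m,
           config$cell$L0_mean_m, config$ros$n_events, config$ros$threshold)
  if (any(!is.finite(pos)) || any(pos <= 0))
    cfg_err("medium, chamber, cell and ros values must be strictly positive")
  if (any(unlist(config$noise) < 0)) cfg_err("noise SDs must be >= 0")
  if (config$cohort$n_cells_zeta < 2L) cfg_err("n_cells_zeta must be >= 2")
  if (is.unsorted(config$cohort$days, strictly = TRUE))
    cfg_err("cohort days must be strictly increasing")
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> estimate -> summarize on a validated configuration
#' and writes the artifact set: `cohort_truth.csv` (ground truth, kept apart
#' from measurements), `zeta_sweeps.csv`, `elongation_sweeps.csv`,
#' `estimates_zeta.csv`, `estimates_mu.csv`, `summaries.csv`,
#' `comparisons.csv`, `ros_series.csv`, `headlines.json`, and a
#' `manifest.json` recording the config hash, seed and file list. Re-running
#' with the same config and seed reproduces identical outputs.
#'
#' Stages can be disabled via `config$stages`; a disabled estimate/summarize
#' stage reads nothing and writes nothing downstream of it.
#'
#' @param config Configuration list (validated with [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return The manifest, invisibly: a list with `config_hash`, `seed`,
#'   `files`, `headlines`, and the in-memory `results` (tibbles).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  med <- medium(config$medium$permittivity,
                convert_units(config$medium$viscosity_cP, "cP", "Pa.s"))
  cham <- chamber(config$chamber$d_m, config$chamber$z1_m, config$chamber$z2_m)
  noise <- noise_model(config$noise$velocity_rel_sd,
                       config$noise$position_noise_sd_m,
                       config$noise$length_noise_sd_m)
  design <- cohort_design(days = config$cohort$days,
                          n_cells_zeta = config$cohort$n_cells_zeta,
                          n_cells_elastic = config$cohort$n_cells_elastic,
                          arm = config$arm)
  schedule <- storage_schedule(config$arm,
                               ros_day1_frac = config$ros$day1_positive_frac)
  files <- character(0)
  results <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }

  # -- simulate ---------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    truth <- draw_cohort(design, schedule, seed = config$seed)
    zeta_sweeps <- simulate_zeta_sweeps(truth, cham, med, noise,
                                        seed = config$seed)
    results$truth <- truth; results$zeta_sweeps <- zeta_sweeps
    emit(truth, "cohort_truth.csv")
    emit(zeta_sweeps, "zeta_sweeps.csv")
    if (any(truth$assay == "elasticity")) {
      elong <- simulate_elongation_sweeps(truth, cham, med, noise,
                                          seed = config$seed)
      results$elongation_sweeps <- elong
      emit(elong, "elongation_sweeps.csv")
    }
    ros_days <- schedule$day[is.finite(schedule$ros_positive_frac) &
                               schedule$day %in% design$days]
    if (length(ros_days)) {
      ros_series <- purrr::map_dfr(ros_days, function(d) {
        ev <- simulate_ros(d, schedule, n_events = config$ros$n_events,
                           seed = config$seed)
        tibble::tibble(day = d,
                       n_events = nrow(ev),
                       percent_positive =
                         ros_percent_positive(ev, config$ros$threshold))
      })
      results$ros_series <- ros_series
      emit(ros_series, "ros_series.csv")
    }
  }

  # -- estimate ---------------------------------------------------------
  if (isTRUE(config$stages$estimate)) {
    if (is.null(results$zeta_sweeps))
      stop("data error: estimate stage needs simulated sweeps", call. = FALSE)
    est_z <- estimate_zeta(results$zeta_sweeps, cham, med)
    results$estimates_zeta <- est_z
    emit(est_z, "estimates_zeta.csv")
    low_r <- sum(abs(est_z$pearson_r) < 0.98, na.rm = TRUE)
    if (low_r > 0)
      message("estimate: ", low_r, " zeta fit(s) with |r| < 0.98")
    if (!is.null(results$elongation_sweeps)) {
      est_m <- estimate_elasticity(results$elongation_sweeps, cham, med,
                                   area_model = config$cell$area_model)
      results$estimates_mu <- est_m
      emit(est_m, "estimates_mu.csv")
    }
  }

  # -- summarize --------------------------------------------------------
  if (isTRUE(config$stages$summarize)) {
    if (is.null(results$estimates_zeta))
      stop("data error: summarize stage needs estimates", call. = FALSE)
    days <- design$days
    pooled <- list()
    if (all(c(8, 15, 22) %in% days))
      pooled[["Day 8 to Day 22"]] <- c(8, 15, 22)
    if (all(c(29, 36) %in% days))
      pooled[["Day 29 to Day 36"]] <- c(29, 36)
    zs <- summarize_by_day(results$estimates_zeta, .data$zeta_mV,
                           pooled = if (length(pooled)) pooled else NULL)
    ms <- if (!is.null(results$estimates_mu))
      summarize_by_day(results$estimates_mu, .data$mu_dyne_cm) else NULL
    comparisons <- day_comparisons(results$estimates_zeta,
                                   results$estimates_mu)
    rep <- build_report(zs, ms, comparisons, results$ros_series)
    results$report <- rep
    sum_tab <- dplyr::bind_rows(
      dplyr::mutate(zeta_to_flat(zs), quantity = "zeta_mV"),
      if (!is.null(ms)) dplyr::mutate(zeta_to_flat(ms),
                                      quantity = "mu_dyne_cm")
    )
    emit(sum_tab, "summaries.csv")
    if (!is.null(comparisons)) emit(comparisons, "comparisons.csv")
    jsonlite::write_json(rep$headlines,
                         file.path(out_dir, "headlines.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "headlines.json")
  }

  # -- manifest ---------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "rbclesion",
    version = as.character(utils::packageVersion("rbclesion")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    files = c("config.json", files),
    headlines = if (!is.null(results$report)) results$report$headlines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- results
  invisible(manifest)
}

# flatten a summary tibble for CSV emission (list column -> day range text)
zeta_to_flat <- function(s) {
  tibble::tibble(label = s$label,
                 days = vapply(s$days, function(d)
                   paste(d, collapse = "+"), character(1L)),
                 n = s$n, mean = s$mean, se = s$se)
}

# standard comparison set: day 1 vs each later day (zeta), plateau vs late,
# and day-8 anchored elasticity comparisons
day_comparisons <- function(est_z, est_m = NULL) {
  out <- list()
  days <- sort(unique(est_z$day))
  if (1 %in% days) {
    z1 <- est_z$zeta_mV[est_z$day == 1]
    for (d in setdiff(days, 1)) {
      out[[length(out) + 1L]] <-
        rank_sum_test(z1, est_z$zeta_mV[est_z$day == d],
                      group_a = "zeta day 1", group_b = paste("zeta day", d))
    }
  }
  if (all(c(8, 15, 22, 29, 36) %in% days)) {
    out[[length(out) + 1L]] <- rank_sum_test(
      est_z$zeta_mV[est_z$day %in% c(8, 15, 22)],
      est_z$zeta_mV[est_z$day %in% c(29, 36)],
      group_a = "zeta day 8-22", group_b = "zeta day 29-36")
  }
  if (!is.null(est_m)) {
    mdays <- sort(unique(est_m$day))
    if (8 %in% mdays) {
      m8 <- est_m$mu_dyne_cm[est_m$day == 8]
      for (d in setdiff(mdays, 8)) {
        out[[length(out) + 1L]] <-
          rank_sum_test(m8, est_m$mu_dyne_cm[est_m$day == d],
                        group_a = "mu day 8", group_b = paste("mu day", d))
      }
    }
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}
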