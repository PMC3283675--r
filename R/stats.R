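#' Per-day cohort summaries (mean and standard error)
#'
#' Summarises per-cell estimates by storage day, optionally adding pooled
#' multi-day groups — the published tables report a "Day 29 to Day 36" row
#' and a pooled day 8-22 plateau, both computed here by pooling cells across
#' the member days (pooling over cells, not averaging day means).
#'
#' @param estimates Data frame of per-cell estimates with a `day` column.
#' @param value Column to summarise (tidy-eval), e.g. `zeta_mV` or
#'   `mu_dyne_cm`.
#' @param pooled Named list of day vectors to add as pooled rows, e.g.
#'   `list("Day 29 to Day 36" = c(29, 36))`.
#' @param pool_method `"cells"` (default; pool all member-day cells) or
#'   `"day_means"` (mean of the member day means, SE across day means).
#' @return Tibble of class `"rbl_summary"`: `label`, `days` (list column),
#'   `n`, `mean`, `se`.
#' @examples
#' est <- tibble::tibble(day = rep(c(1, 8), each = 3),
#'                       zeta_mV = c(-15, -14, -14.5, -10, -9.5, -9.7))
#' summarize_by_day(est, zeta_mV)
#' @export
summarize_by_day <- function(estimates, value, pooled = NULL,
                             pool_method = c("cells", "day_means")) {
  pool_method <- match.arg(pool_method)
  stopifnot(is.data.frame(estimates), "day" %in% names(estimates))
  v <- rlang::enquo(value)
  vals <- dplyr::transmute(estimates, day = .data$day,
                           value = !!v)
  vals <- dplyr::filter(vals, is.finite(.data$value))
  one_group <- function(label, days) {
    x <- vals$value[vals$day %in% days]
    if (length(x) < 2L)
      stop("insufficient data: group '", label, "' has fewer than 2 values",
           call. = FALSE)
    tibble::tibble(label = label, days = list(days), n = length(x),
                   mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  days <- sort(unique(vals$day))
  out <- purrr::map_dfr(days, function(d) one_group(paste("Day", d), d))
  if (!is.null(pooled)) {
    stopifnot(!is.null(names(pooled)))
    extra <- purrr::imap_dfr(pooled, function(dd, lab) {
      if (pool_method == "cells") return(one_group(lab, dd))
      per_day <- purrr::map_dbl(dd, function(d)
        mean(vals$value[vals$day == d]))
      tibble::tibble(label = lab, days = list(dd), n = length(per_day),
                     mean = mean(per_day),
                     se = stats::sd(per_day) / sqrt(length(per_day)))
    })
    out <- dplyr::bind_rows(out, extra)
  }
  class(out) <- c("rbl_summary", class(out))
  out
}

#' Two-tailed Wilcoxon rank-sum comparison of two groups
#'
#' The cohort comparisons use the Wilcoxon (Mann-Whitney) rank-sum test at
#' the two-tailed 0.05 level. The exact null distribution is enumerated when
#' the pooled sample is small (`n_a + n_b <= 12`) and tie-free; otherwise the
#' normal approximation with tie and continuity corrections is used. The
#' branch taken is recorded in the result.
#'
#' @param a,b Numeric vectors (>= 2 finite values each).
#' @param group_a,group_b Labels for the report row.
#' @param exact Override the automatic exact/approximate switch.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return One-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `statistic`
#'   (Mann-Whitney U for `a`), `p_two_tailed`, `method`, `significant`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rank_sum_test <- function(a, b, group_a = "a", group_b = "b",
                          exact = NULL, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    statistic = unname(wt$statistic),
    p_two_tailed = wt$p.value,
    method = if (exact) "exact" else "normal approximation",
    significant = wt$p.value < alpha
  )
}

#' Percent change relative to a reference value
#'
#' `100 * (other - reference) / abs(reference)`, sign retained. Headline
#' storage-lesion figures are magnitude decays/rises; see
#' [percent_magnitude_change()] for those.
#'
#' @param reference Reference (baseline) value; must be nonzero.
#' @param other Comparison value.
#' @param round If `TRUE`, round to the nearest integer (report style).
#' @return Percent change (numeric).
#' @examples
#' percent_change(4.1e-4, 9.6e-4, round = TRUE)  # +134
#' @export
percent_change <- function(reference, other, round = FALSE) {
  stopifnot(is.numeric(reference), is.numeric(other))
  if (any(reference == 0))
    stop("reference value must be nonzero", call. = FALSE)
  pc <- 100 * (other - reference) / abs(reference)
  if (round) round(pc) else pc
}

#' Percent change in magnitude
#'
#' For signed quantities like zeta potential (negative throughout storage),
#' the published headlines describe the change in magnitude: a decay from
#' -14.5 to -8.5 mV is a 41% magnitude decrease. Returns
#' `100 * (|other| - |reference|) / |reference|` (negative = decay).
#'
#' @inheritParams percent_change
#' @export
percent_magnitude_change <- function(reference, other, round = FALSE) {
  percent_change(abs(reference), abs(other), round = round)
}

#' Percent of ROS-positive events above a gating threshold
#'
#' @param events Event tibble from [simulate_ros()] (or any data frame with
#'   an `intensity` column).
#' @param threshold Gate intensity; defaults to the threshold attribute
#'   carried by the event set, else must be given.
#' @return Percent of events with intensity above the threshold.
#' @export
ros_percent_positive <- function(events, threshold = attr(events, "threshold")) {
  stopifnot(is.data.frame(events), "intensity" %in% names(events))
  if (nrow(events) == 0L)
    stop("no events", call. = FALSE)
  if (is.null(threshold) || !is.numeric(threshold))
    stop("a gating threshold is required", call. = FALSE)
  100 * mean(events$intensity > threshold)
}

#' Assemble the cohort report
#'
#' Collects the pipeline's cohort-level outputs into deterministic report
#' tables: a zeta table shaped like the published storage-time tables (day
#' rows plus a pooled "Day 29 to Day 36" row), an elasticity time course, the
#' comparison table, the ROS percent-positive series, and the headline
#' percent-change block with keys `zeta_decay_total_pct`,
#' `zeta_decay_week1_pct`, `elasticity_increase_pct`, `ros_rise_week1_rel`,
#' `ros_rise_late_rel`.
#'
#' Headline definitions: total zeta decay is the magnitude decrease from
#' day 1 to the pooled final (day 29-36) group; week-1 decay is from day 1 to
#' the pooled day 8-22 plateau; the elasticity rise baselines at day 8, the
#' first elasticity measurement; ROS rises are relative changes in
#' percent-positive day 1 to 8 and day 8 to 36.
#'
#' @param zeta_summary [summarize_by_day()] output for `zeta_mV`, with pooled
#'   rows `"Day 8 to Day 22"` and `"Day 29 to Day 36"` present when the
#'   cohort covers those days.
#' @param mu_summary Optional [summarize_by_day()] output for `mu_dyne_cm`.
#' @param comparisons Optional tibble of [rank_sum_test()] rows.
#' @param ros_series Optional tibble with columns `day`,
#'   `percent_positive`.
#' @return A list of class `"rbl_report"`: `zeta_table`, `mu_table`,
#'   `comparisons`, `ros_series`, `headlines` (named list).
#' @export
build_report <- function(zeta_summary, mu_summary = NULL, comparisons = NULL,
                         ros_series = NULL) {
  stopifnot(inherits(zeta_summary, "rbl_summary"))
  get_mean <- function(summary, label) {
    i <- match(label, summary$label)
    if (is.na(i)) NULL else summary$mean[i]
  }
  headlines <- list()
  z1 <- get_mean(zeta_summary, "Day 1")
  z_plateau <- get_mean(zeta_summary, "Day 8 to Day 22")
  z_final <- get_mean(zeta_summary, "Day 29 to Day 36")
  if (!is.null(z1) && !is.null(z_final))
    headlines$zeta_decay_total_pct <- -percent_magnitude_change(z1, z_final)
  if (!is.null(z1) && !is.null(z_plateau))
    headlines$zeta_decay_week1_pct <- -percent_magnitude_change(z1, z_plateau)
  if (!is.null(mu_summary)) {
    m8 <- get_mean(mu_summary, "Day 8")
    m36 <- get_mean(mu_summary, "Day 36")
    if (!is.null(m8) && !is.null(m36))
      headlines$elasticity_increase_pct <- percent_change(m8, m36)
  }
  if (!is.null(ros_series)) {
    stopifnot(all(c("day", "percent_positive") %in% names(ros_series)))
    p <- function(d) {
      i <- match(d, ros_series$day)
      if (is.na(i)) NULL else ros_series$percent_positive[i]
    }
    if (!is.null(p(1)) && !is.null(p(8)))
      headlines$ros_rise_week1_rel <- percent_change(p(1), p(8))
    if (!is.null(p(8)) && !is.null(p(36)))
      headlines$ros_rise_late_rel <- percent_change(p(8), p(36))
  }
  structure(list(zeta_table = zeta_summary, mu_table = mu_summary,
                 comparisons = comparisons, ros_series = ros_series,
                 headlines = headlines),
            class = "rbl_report")
}

#' @export
print.rbl_report <- function(x, ...) {
  cat("RBC storage-lesion cohort report\n\nZeta potential (mV):\n")
  print(as.data.frame(x$zeta_table[, c("label", "n", "mean", "se")]),
        row.names = FALSE)
  if (!is.null(x$mu_table)) {
    cat("\nApparent elasticity (dyne/cm):\n")
    print(as.data.frame(x$mu_table[, c("label", "n", "mean", "se")]),
          row.names = FALSE)
  }
  if (!is.null(x$ros_series)) {
    cat("\nROS percent-positive:\n")
    print(as.data.frame(x$ros_series), row.names = FALSE)
  }
  if (length(x$headlines)) {
    cat("\nHeadlines:\n")
    for (k in names(x$headlines))
      cat(sprintf("  %s: %.1f\n", k, x$headlines[[k]]))
  }
  invisible(x)
}
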