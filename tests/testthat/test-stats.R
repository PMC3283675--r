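test_that("day summaries compute mean and standard error per group", {
  est <- tibble::tibble(day = c(1, 1, 1, 8, 8),
                        zeta_mV = c(-10, -10, -10, -9, -11))
  s <- summarize_by_day(est, zeta_mV)
  expect_equal(s$mean, c(-10, -10))
  expect_equal(s$se, c(0, 1))
  expect_equal(s$n, c(3L, 2L))
  expect_equal(s$label, c("Day 1", "Day 8"))
  expect_error(summarize_by_day(tibble::tibble(day = 1, zeta_mV = -10),
                                zeta_mV), "insufficient data")
})

test_that("pooled rows pool cells by default, day means on request", {
  est <- tibble::tibble(day = rep(c(8, 15, 22), times = c(2, 2, 4)),
                        zeta_mV = c(-9, -11, -10, -10, -9, -9, -9, -9))
  pooled <- list("Day 8 to Day 22" = c(8, 15, 22))
  s_cells <- summarize_by_day(est, zeta_mV, pooled = pooled)
  row <- s_cells[s_cells$label == "Day 8 to Day 22", ]
  expect_equal(row$n, 8L)
  expect_equal(row$mean, mean(est$zeta_mV))  # -9.5, weighted by cells
  s_days <- summarize_by_day(est, zeta_mV, pooled = pooled,
                             pool_method = "day_means")
  row2 <- s_days[s_days$label == "Day 8 to Day 22", ]
  expect_equal(row2$mean, mean(c(-10, -10, -9)))  # unweighted day means
  # published plateau: both conventions give -10.07 on the printed means
  printed <- tibble::tibble(day = rep(c(8, 15, 22), each = 2),
                            zeta_mV = rep(c(-9.7, -10.3, -10.2), each = 2))
  sp <- summarize_by_day(printed, zeta_mV, pooled = pooled)
  expect_equal(sp$mean[sp$label == "Day 8 to Day 22"], -10.0667,
               tolerance = 1e-4)
})

test_that("summary SE shrinks as 1/sqrt(n) on resampled cohorts", {
  set.seed(8)
  pop <- stats::rnorm(4000, -10, 2)
  se_n <- function(n) {
    est <- tibble::tibble(day = 1, zeta_mV = pop[seq_len(n)])
    summarize_by_day(est, zeta_mV)$se
  }
  expect_equal(se_n(4000) / se_n(250), sqrt(250 / 4000), tolerance = 0.25)
})

test_that("exact rank-sum branch reproduces the enumerated null", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_two_tailed, 0.1)
  expect_equal(res$method, "exact")
  expect_false(res$significant)

  set.seed(12)
  for (n_a in 2:4) {
    for (n_b in 2:(min(10 - n_a, 5))) {
      a <- stats::rnorm(n_a); b <- stats::rnorm(n_b, 0.5)
      expect_equal(rank_sum_test(a, b)$p_two_tailed,
                   enumerate_wilcoxon_p(a, b),
                   tolerance = 1e-12,
                   info = sprintf("n_a=%d n_b=%d", n_a, n_b))
    }
  }
})

test_that("rank-sum test handles ties, identity, and monotone transforms", {
  ident <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(ident$p_two_tailed, 0.99)
  expect_equal(ident$method, "normal approximation")  # ties force approx

  set.seed(2)
  a <- stats::rnorm(15); b <- stats::rnorm(12, 0.8)
  p0 <- rank_sum_test(a, b)$p_two_tailed
  expect_equal(rank_sum_test(exp(a), exp(b))$p_two_tailed, p0)
  expect_equal(rank_sum_test(a^3 + 5 * a, b^3 + 5 * b)$p_two_tailed, p0)
  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")
})

test_that("day-1 vs day-8 zeta cohorts separate at p < 0.001", {
  hits <- vapply(1:20, function(s) {
    truth <- draw_cohort(cohort_design(days = c(1L, 8L)), seed = s)
    est <- estimate_zeta(simulate_zeta_sweeps(truth, seed = s))
    rank_sum_test(est$zeta_mV[est$day == 1],
                  est$zeta_mV[est$day == 8])$p_two_tailed < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("percent change follows its definition, including the sign convention", {
  expect_equal(percent_change(4.1e-4, 9.6e-4, round = TRUE), 134)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(-14.5, -10.1), 100 * 4.4 / 14.5)
  expect_equal(percent_magnitude_change(-14.5, -10.1, round = TRUE), -30)
  expect_equal(percent_magnitude_change(-14.5, -8.5), -100 * 6 / 14.5)
  # direction antisymmetry up to the |reference| normalisation
  expect_equal(percent_change(10, 12), -percent_change(10, 8))
  expect_error(percent_change(0, 5), "nonzero")
})

test_that("ROS percent-positive counts events above the gate", {
  ev <- tibble::tibble(intensity = c(rep(1, 19800), rep(100, 200)))
  expect_equal(ros_percent_positive(ev, threshold = 40), 1.0)
  expect_equal(ros_percent_positive(ev, threshold = 1e6), 0)
  expect_error(ros_percent_positive(ev[0, ], threshold = 40), "no events")
  expect_error(ros_percent_positive(ev), "threshold")
})

test_that("report assembles tables, headline block, and is deterministic", {
  est <- tibble::tibble(
    day = rep(c(1, 8, 15, 22, 29, 36), each = 4),
    zeta_mV = rep(c(-14.5, -9.7, -10.3, -10.2, -8.5, -8.5), each = 4) +
      rep(c(-0.1, 0.1, -0.2, 0.2), times = 6))
  zs <- summarize_by_day(est, zeta_mV,
                         pooled = list("Day 8 to Day 22" = c(8, 15, 22),
                                       "Day 29 to Day 36" = c(29, 36)))
  mu <- tibble::tibble(day = rep(c(8, 36), each = 3),
                       mu_dyne_cm = c(4.0e-4, 4.1e-4, 4.2e-4,
                                      9.5e-4, 9.6e-4, 9.7e-4))
  ms <- summarize_by_day(mu, mu_dyne_cm)
  ros <- tibble::tibble(day = c(1, 8, 36),
                        percent_positive = c(20, 32, 37.12))
  rep1 <- build_report(zs, ms, ros_series = ros)
  expect_setequal(names(rep1$headlines),
                  c("zeta_decay_total_pct", "zeta_decay_week1_pct",
                    "elasticity_increase_pct", "ros_rise_week1_rel",
                    "ros_rise_late_rel"))
  expect_equal(rep1$headlines$zeta_decay_total_pct, 100 * 6 / 14.5,
               tolerance = 1e-10)
  expect_equal(rep1$headlines$elasticity_increase_pct, 100 * 5.5 / 4.1)
  expect_equal(rep1$headlines$ros_rise_week1_rel, 60)
  expect_equal(rep1$headlines$ros_rise_late_rel, 16)
  expect_true("Day 29 to Day 36" %in% rep1$zeta_table$label)
  rep2 <- build_report(zs, ms, ros_series = ros)
  expect_identical(rep1$headlines, rep2$headlines)
  # summaries-only report
  rep3 <- build_report(zs)
  expect_null(rep3$mu_table)
  expect_false("elasticity_increase_pct" %in% names(rep3$headlines))
})
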