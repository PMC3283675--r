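test_that("default schedule encodes the published storage-time means", {
  s <- storage_schedule()
  expect_equal(s$day, c(1L, 8L, 15L, 22L, 29L, 36L))
  expect_equal(s$zeta_mean_mV, c(-14.5, -9.7, -10.3, -10.2, -8.5, -8.5))
  expect_true(all(s$zeta_mean_mV < 0))
  expect_equal(s$zeta_sd_mV, s$zeta_se_mV * sqrt(40))
  expect_equal(s$mu_mean_dyne_cm[s$day == 8], 4.1e-4)
  expect_equal(s$mu_mean_dyne_cm[s$day == 36], 9.6e-4)
  expect_true(is.na(s$mu_mean_dyne_cm[s$day == 1]))
  # ROS fractions rise x1.60 over week 1 and x1.16 from day 8 to 36
  p <- s$ros_positive_frac
  expect_equal(p[s$day == 8] / p[s$day == 1], 1.60)
  expect_equal(p[s$day == 36] / p[s$day == 8], 1.16)
  expect_true(all(diff(p) > 0))

  l <- storage_schedule("leukodepleted")
  expect_equal(l$day, c(1L, 8L, 15L))
  expect_equal(l$zeta_mean_mV, c(-14.0, -9.5, -10.0))
  expect_equal(l$zeta_sd_mV, l$zeta_se_mV * sqrt(20))
})

test_that("cohort draws are deterministic, schedule-checked, and sized by design", {
  des <- cohort_design(n_cells_zeta = 4L, n_cells_elastic = 2L)
  c1 <- draw_cohort(des, seed = 5)
  c2 <- draw_cohort(des, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1, draw_cohort(des, seed = 6)))

  expect_equal(sum(c1$assay == "zeta"), 6L * 4L)
  expect_equal(sum(c1$assay == "elasticity"), 5L * 2L)  # no day-1 elasticity
  expect_true(all(c1$L0_m > 0))
  expect_true(all(c1$mu_true_dyne_cm[c1$assay == "elasticity"] > 0))

  tiny <- draw_cohort(cohort_design(days = 1L, n_cells_zeta = 2L), seed = 1)
  expect_equal(nrow(tiny), 2L)

  expect_error(draw_cohort(cohort_design(days = c(1L, 99L)), seed = 1),
               "schedule error")
})

test_that("day-1 cohort mean zeta obeys the CLT around the scheduled mean", {
  des <- cohort_design(days = 1L)
  means <- vapply(1:10, function(s)
    mean(draw_cohort(des, seed = s)$zeta_true_mV, na.rm = TRUE), numeric(1))
  # scheduled: mean -14.5, between-cell SD 0.7*sqrt(40), so SE at n=40 is 0.7
  expect_lt(abs(mean(means) + 14.5), 3 * 0.7 / sqrt(10))
})

test_that("noiseless sweeps are exactly proportional with the expected speed scale", {
  cells <- draw_cohort(cohort_design(days = 1L, n_cells_zeta = 2L), seed = 2)
  cells$zeta_true_mV <- -14.5
  sw <- simulate_zeta_sweeps(cells, noise = noise_model(velocity_rel_sd = 0),
                             seed = 2)
  one <- dplyr::filter(sw, cell_id == cells$cell_id[1])
  expect_equal(one$velocity_m_s / one$voltage_V,
               rep(one$velocity_m_s[1] / one$voltage_V[1], 6))
  # -14.5 mV in a 1 cm chamber at 50 V: |v| = 46.6 um/s
  v50 <- abs(one$velocity_m_s[one$voltage_V == 50])
  expect_equal(convert_units(v50, "m/s", "um/s"), 46.6, tolerance = 1e-3)
  expect_true(all(sw$velocity_m_s < 0))  # negative cells
})

test_that("per-cell noise substreams are independent and reproducible", {
  cells <- draw_cohort(cohort_design(days = 1L, n_cells_zeta = 3L), seed = 4)
  cells$zeta_true_mV <- -12
  sw1 <- simulate_zeta_sweeps(cells, seed = 4)
  sw2 <- simulate_zeta_sweeps(cells, seed = 4)
  expect_identical(sw1, sw2)
  by_cell <- split(sw1$velocity_m_s, sw1$cell_id)
  expect_false(identical(by_cell[[1]], by_cell[[2]]))
  # regenerating a subset reproduces the same measurements
  sub <- simulate_zeta_sweeps(cells[1:2, ], seed = 4)
  expect_equal(dplyr::filter(sw1, cell_id %in% cells$cell_id[1:2]), sub)
})

test_that("elongation sweeps are monotone and scale inversely with stiffness", {
  base <- tibble::tibble(cell_id = c("soft", "stiff"), day = 8L,
                         arm = "standard", assay = "elasticity",
                         zeta_true_mV = NA_real_,
                         mu_true_dyne_cm = c(4.1e-4, 9.6e-4), L0_m = 8e-6)
  sw <- simulate_elongation_sweeps(base,
                                   noise = noise_model(length_noise_sd_m = 0),
                                   seed = 1)
  soft <- dplyr::filter(sw, cell_id == "soft")
  stiff <- dplyr::filter(sw, cell_id == "stiff")
  expect_true(all(diff(soft$length_m) > 0))
  dl_ratio <- (stiff$length_m - 8e-6) / (soft$length_m - 8e-6)
  expect_equal(dl_ratio, rep(4.1 / 9.6, 6), tolerance = 1e-9)
})

test_that("ROS event sets respect edge-case positive fractions", {
  sched <- storage_schedule()
  sched$ros_positive_frac[sched$day == 1] <- 0
  ev0 <- simulate_ros(1, sched, n_events = 5000L, seed = 2)
  expect_lt(ros_percent_positive(ev0), 0.5)  # only threshold false positives
  sched$ros_positive_frac[sched$day == 1] <- 1
  ev1 <- simulate_ros(1, sched, n_events = 5000L, seed = 2)
  expect_gt(ros_percent_positive(ev1), 90)   # minus threshold misses
  expect_error(simulate_ros(99, storage_schedule(), seed = 1),
               "schedule error")
})

test_that("velocity noise scales the per-cell measurement error linearly", {
  # with multiplicative velocity noise and fixed truth, the spread of the
  # recovered zeta is proportional to the noise SD; the day-mean SE follows
  # sqrt(between-cell var + measurement var / 1) / sqrt(n)
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:300), day = 1L,
                          arm = "standard", assay = "zeta",
                          zeta_true_mV = -12, mu_true_dyne_cm = NA_real_,
                          L0_m = 8e-6)
  sd_at <- function(rel_sd, seed) {
    sw <- simulate_zeta_sweeps(cells,
                               noise = noise_model(velocity_rel_sd = rel_sd),
                               seed = seed)
    stats::sd(estimate_zeta(sw)$zeta_mV)
  }
  ratio <- sd_at(0.16, 21) / sd_at(0.04, 21)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
  # under the calibrated schedule the day mean is between-cell dominated:
  # quadrupled measurement noise barely moves the cohort SE
  truth <- draw_cohort(cohort_design(days = 1L), seed = 23)
  se_of <- function(rel_sd) {
    est <- estimate_zeta(simulate_zeta_sweeps(
      truth, noise = noise_model(velocity_rel_sd = rel_sd), seed = 23))
    stats::sd(est$zeta_mV) / sqrt(nrow(est))
  }
  expect_lt(se_of(0.16) / se_of(0.04), 1.5)
})

test_that("full loop recovers the scheduled day means at the protocol sample sizes", {
  truth <- draw_cohort(cohort_design(), seed = 31)
  est_z <- estimate_zeta(simulate_zeta_sweeps(truth, seed = 31))
  est_m <- estimate_elasticity(simulate_elongation_sweeps(truth, seed = 31))
  s <- storage_schedule()
  for (d in c(1L, 8L, 29L)) {
    got <- mean(est_z$zeta_mV[est_z$day == d])
    expect_lt(abs(got - s$zeta_mean_mV[s$day == d]),
              2 * s$zeta_se_mV[s$day == d] +
                2 * s$zeta_sd_mV[s$day == d] / sqrt(40))
  }
  got8 <- mean(est_m$mu_dyne_cm[est_m$day == 8])
  expect_lt(abs(got8 - 4.1e-4), 3 * 0.6e-4)
})
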