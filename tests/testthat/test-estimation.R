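test_that("proportional fit matches closed form and the grid-search oracle", {
  f <- fit_proportional(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$pearson_r, 1)

  f2 <- fit_proportional(c(1, 2, 3), c(2.1, 3.9, 6.0))
  expect_equal(f2$slope, 27.9 / 14)  # sum(x*y) / sum(x^2)
  expect_equal(f2$slope, grid_slope(c(1, 2, 3), c(2.1, 3.9, 6.0)),
               tolerance = 1e-4)

  expect_equal(fit_proportional(c(1, 2, 3), c(0, 0, 0))$slope, 0)
  expect_error(fit_proportional(c(0, 0), c(1, 2)), "degenerate fit")
  expect_error(fit_proportional(1, 2), "insufficient data")

  set.seed(42)
  for (i in 1:5) {
    x <- stats::runif(6, 0.5, 3)
    y <- 1.7 * x + stats::rnorm(6, 0, 0.3)
    expect_equal(fit_proportional(x, y)$slope, grid_slope(x, y),
                 tolerance = 1e-4)
  }
})

test_that("tidy and glance expose the proportional fit as tibbles", {
  set.seed(3)
  x <- 1:6; y <- 2 * x + stats::rnorm(6, 0, 0.2)
  f <- fit_proportional(x, y)
  td <- generics::tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, "slope")
  expect_equal(td$estimate, f$slope)
  # std.error agrees with the no-intercept lm
  lm_se <- summary(stats::lm(y ~ x + 0))$coefficients[1, 2]
  expect_equal(td$std.error, lm_se, tolerance = 1e-10)
  gl <- generics::glance(f)
  expect_equal(gl$nobs, 6L)
  expect_equal(gl$r.squared, f$pearson_r^2)
})

test_that("free-intercept diagnostic mode reports but does not replace the slope", {
  set.seed(5)
  x <- 1:6; y <- 2 * x + 0.5 + stats::rnorm(6, 0, 0.1)
  f <- fit_proportional(x, y, intercept = TRUE)
  expect_equal(f$slope, sum(x * y) / sum(x^2))
  expect_equal(f$diagnostic$slope, unname(stats::coef(stats::lm(y ~ x))[2]))
  expect_gt(f$diagnostic$intercept, 0)
})

test_that("zeta estimates invert noiseless forward sweeps exactly", {
  sw <- noiseless_zeta_sweep(-14.5)
  est <- estimate_zeta(sw)
  expect_equal(est$zeta_mV, -14.5, tolerance = 1e-6)
  expect_equal(abs(est$pearson_r), 1, tolerance = 1e-12)
  expect_equal(est$n_points, 6L)

  # uncharged cell: no migration at any voltage
  sw0 <- dplyr::mutate(sw, velocity_m_s = 0)
  expect_equal(estimate_zeta(sw0)$zeta_mV, 0)
})

test_that("zeta estimation is equivariant in velocity scale and electrode distance", {
  sw <- noiseless_zeta_sweep(-10)
  z0 <- estimate_zeta(sw)$zeta_mV
  z2 <- estimate_zeta(dplyr::mutate(sw, velocity_m_s = 3 * velocity_m_s))$zeta_mV
  expect_equal(z2, 3 * z0, tolerance = 1e-9)
  # doubling d halves every field, doubling the fitted mobility
  zd <- estimate_zeta(sw, chamber = chamber(electrode_separation = 2e-2))$zeta_mV
  expect_equal(zd, 2 * z0, tolerance = 1e-9)
})

test_that("zeta estimation is unbiased under multiplicative velocity noise", {
  # Monte-Carlo: proportional OLS with symmetric relative noise is unbiased
  cells <- tibble::tibble(cell_id = sprintf("c%04d", 1:1000), day = 1L,
                          arm = "standard", assay = "zeta",
                          zeta_true_mV = -10, mu_true_dyne_cm = NA_real_,
                          L0_m = 8e-6)
  sw <- simulate_zeta_sweeps(cells, noise = noise_model(velocity_rel_sd = 0.05),
                             seed = 9)
  est <- estimate_zeta(sw)
  expect_equal(mean(est$zeta_mV), -10, tolerance = 0.1 / 10)
})

test_that("elasticity estimates invert noiseless forward sweeps exactly", {
  sw <- noiseless_elong_sweep(4.1e-4)
  est <- estimate_elasticity(sw)
  expect_equal(est$mu_dyne_cm, 4.1e-4, tolerance = 1e-6)
  expect_equal(est$mu_N_m, 4.1e-7, tolerance = 1e-6)
  expect_equal(abs(est$pearson_r), 1, tolerance = 1e-12)

  # halving every deformation at fixed velocities doubles the stiffness
  half <- dplyr::mutate(sw, length_m = rest_length_m +
                          (length_m - rest_length_m) / 2)
  expect_equal(estimate_elasticity(half)$mu_dyne_cm, 2 * 4.1e-4,
               tolerance = 1e-6)
})

test_that("forward-inverse consistency holds across the physiological range", {
  for (z in c(-50, -25, -8.5, -1)) {
    expect_equal(estimate_zeta(noiseless_zeta_sweep(z))$zeta_mV, z,
                 tolerance = 1e-6)
  }
  for (m in c(2e-4, 4.6e-4, 9.6e-4, 2e-3)) {
    expect_equal(estimate_elasticity(noiseless_elong_sweep(m))$mu_dyne_cm, m,
                 tolerance = 1e-6)
  }
})

test_that("non-physical and degenerate elasticity sweeps are rejected", {
  sw <- noiseless_elong_sweep(4.1e-4)
  rigid <- dplyr::mutate(sw, length_m = rest_length_m)
  expect_error(estimate_elasticity(rigid), "non-physical")
  shrink <- dplyr::mutate(sw, length_m = rest_length_m -
                            (length_m - rest_length_m))
  expect_error(estimate_elasticity(shrink), "non-physical")
  expect_error(estimate_elasticity(sw[1:2, ]), "insufficient data")
  expect_error(estimate_zeta(noiseless_zeta_sweep(-10)[1:2, ]),
               "insufficient data")
})

test_that("estimators carry per-cell metadata and group multiple cells", {
  sw <- dplyr::bind_rows(
    dplyr::mutate(noiseless_zeta_sweep(-14.5, cell_id = "a"), day = 1L,
                  arm = "standard"),
    dplyr::mutate(noiseless_zeta_sweep(-9.7, cell_id = "b"), day = 8L,
                  arm = "standard")
  )
  est <- estimate_zeta(sw)
  expect_equal(nrow(est), 2L)
  expect_equal(est$day[match(c("a", "b"), est$cell_id)], c(1L, 8L))
  expect_equal(sort(est$zeta_mV), c(-14.5, -9.7), tolerance = 1e-6)
  expect_error(estimate_zeta(dplyr::select(sw, -voltage_V)), "missing column")
})
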