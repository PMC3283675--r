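# Shared fixtures and independent oracles for the suite.

default_med <- medium()
default_cham <- chamber()

# Brute-force grid minimiser of sum((y - s*x)^2): independent oracle for the
# closed-form proportional slope.
grid_slope <- function(x, y, span = 2, n_grid = 400001L) {
  s0 <- sum(x * y) / sum(x^2)
  width <- max(abs(s0), 1) * span
  grid <- seq(s0 - width, s0 + width, length.out = n_grid)
  sse <- vapply(grid, function(s) sum((y - s * x)^2), numeric(1L))
  grid[which.min(sse)]
}

# Exact two-tailed Wilcoxon rank-sum p-value by full enumeration of all
# C(n, n_a) assignments of the pooled ranks (tie-free data only).
enumerate_wilcoxon_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  stopifnot(anyDuplicated(pooled) == 0L)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2L, function(idx)
    sum(r[idx]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Forward-simulated noiseless zeta sweep for a single cell.
noiseless_zeta_sweep <- function(zeta_mV, voltages = seq(30, 80, 10),
                                 cham = default_cham, med = default_med,
                                 cell_id = "c1") {
  E <- field_from_voltage(voltages, cham)
  v <- mobility_from_zeta(convert_units(zeta_mV, "mV", "V"), med) * E
  tibble::tibble(cell_id = cell_id, voltage_V = voltages, velocity_m_s = v)
}

# Forward-simulated noiseless elongation sweep for a single cell.
noiseless_elong_sweep <- function(mu_dyne_cm, L0 = 8e-6,
                                  velocities = seq(140e-6, 290e-6,
                                                   length.out = 6),
                                  cham = default_cham, med = default_med,
                                  cell_id = "c1") {
  mu <- convert_units(mu_dyne_cm, "dyne/cm", "N/m")
  dL <- deformation_from_velocity(mu, med, velocities, cell_geometry(L0),
                                  cham$z_eq)
  tibble::tibble(cell_id = cell_id, velocity_m_s = velocities,
                 length_m = L0 + dL, rest_length_m = L0)
}
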