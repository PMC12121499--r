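test_that("point-dipole coupling matches the closed form and its geometry limits", {
  # parallel dipoles perpendicular to the separation: kappa = 1
  p1 <- toy_pigment("a", c(0, 0, 0), c(0, 1, 0))
  p2 <- toy_pigment("b", c(8, 0, 0), c(0, 1, 0))
  v <- point_dipole_coupling(p1, p2, screening_f = 1)
  expect_equal(v, 5034.1 * 1 * 1 * 4 * 4 / 8^3, tolerance = 1e-10)
  expect_equal(v, 157.3, tolerance = 1e-4)

  # mutually perpendicular dipoles, both perpendicular to R: kappa = 0
  p3 <- toy_pigment("c", c(8, 0, 0), c(0, 0, 1))
  expect_equal(point_dipole_coupling(p1, p3, 1), 0, tolerance = 1e-10)

  # collinear head-to-tail (kappa = -2) is exactly -2x the kappa = 1 value
  p4 <- toy_pigment("d", c(0, 0, 0), c(1, 0, 0))
  p5 <- toy_pigment("e", c(8, 0, 0), c(1, 0, 0))
  expect_equal(point_dipole_coupling(p4, p5, 1), -2 * v, tolerance = 1e-10)

  expect_error(point_dipole_coupling(p1, toy_pigment("f", c(1.5, 0, 0), c(0, 1, 0))),
               "point-dipole")
})

test_that("coupling is symmetric, |kappa| bounded, and scales as R^-3", {
  set.seed(5)
  for (rep in 1:8) {
    a1 <- c(runif(2, -1, 1), 0); a2 <- c(runif(2, -1, 1), 0)
    if (all(a1 == 0)) a1 <- c(1, 0, 0)
    if (all(a2 == 0)) a2 <- c(0, 1, 0)
    R <- runif(1, 6, 15)
    p1 <- toy_pigment("a", c(0, 0, 0), a1)
    p2 <- toy_pigment("b", c(0, 0, R), a2)
    v <- point_dipole_coupling(p1, p2)
    expect_equal(point_dipole_coupling(p2, p1), v, tolerance = 1e-12)
    # |kappa| <= 2 bounds |V| by the collinear value
    expect_lte(abs(v), 2 * 5034.1 * 0.72 * 16 / R^3 + 1e-9)
    # uniform scaling of the separation
    p3 <- toy_pigment("c", c(0, 0, 2 * R), a2)
    expect_equal(point_dipole_coupling(p1, p3), v / 8, tolerance = 1e-9)
  }
})

test_that("build_system converts wavenumber couplings and rejects bad input", {
  se <- data.frame(pigment_id = c("P_D1", "P_D2"), value = c(1.946, 1.946),
                   unit = "eV")
  cp <- data.frame(pigment_i = "P_D1", pigment_j = "P_D2", value = 77,
                   unit = "cm-1")
  sys <- build_system(se, cp, model_label = "WL")
  expect_equal(sys$couplings["P_D1", "P_D2"], 77 / 8065.544, tolerance = 1e-12)
  expect_equal(round(sys$couplings["P_D1", "P_D2"], 6), 0.009547)

  # eV couplings pass through unchanged
  cp_ev <- data.frame(pigment_i = "P_D1", pigment_j = "P_D2",
                      value = 0.0120277, unit = "eV")
  expect_equal(build_system(se, cp_ev)$couplings["P_D2", "P_D1"], 0.0120277)

  # asymmetric coupling entries are an error, not an average
  cp_bad <- data.frame(pigment_i = c("P_D1", "P_D2"),
                       pigment_j = c("P_D2", "P_D1"),
                       value = c(0.010, 0.012), unit = "eV")
  expect_error(build_system(se, cp_bad), "asymmetric")

  expect_error(build_system(se[, c("pigment_id", "value")], cp), "unit")
  cp_off <- data.frame(pigment_i = "P_D1", pigment_j = "Chl_D1", value = 1,
                       unit = "cm-1")
  expect_error(build_system(se, cp_off), "Chl_D1")
})

test_that("diagonalize matches the analytic dimer and its limits", {
  # tabulated dimer: energies from the Chl d model, 97 cm-1 coupling
  se <- data.frame(pigment_id = c("a", "b"), value = c(1.936, 1.904),
                   unit = "eV")
  cp <- data.frame(pigment_i = "a", pigment_j = "b", value = 97, unit = "cm-1")
  st <- diagonalize(build_system(se, cp))
  expect_equal(st$energies, c(1.9000, 1.9400), tolerance = 1e-4)

  # random dimers against the closed form, to 1e-10
  set.seed(12)
  for (rep in 1:25) {
    e <- runif(2, 1.5, 2.2)
    v <- runif(1, -0.05, 0.05)
    sys <- exciton_system(c("x", "y"), e,
                          matrix(c(0, v, v, 0), 2, 2))
    st <- diagonalize(sys)
    expect_equal(st$energies, dimer_eigenvalues(e[1], e[2], v),
                 tolerance = 1e-10)
    # trace conservation and orthonormal rows
    expect_equal(sum(st$energies), sum(e), tolerance = 1e-8)
    expect_equal(st$coefficients %*% t(st$coefficients), diag(2),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }

  # zero coupling: eigenvalues are the site energies, fully localized
  sys0 <- exciton_system(c("x", "y", "z"), c(1.9, 1.8, 2.0),
                         matrix(0, 3, 3))
  st0 <- diagonalize(sys0)
  expect_equal(st0$energies, c(1.8, 1.9, 2.0))
  expect_equal(st0$participation_ratios, rep(1, 3), tolerance = 1e-9)

  # degenerate dimer: splitting exactly 2V, both states fully delocalized
  v <- 0.01
  std <- diagonalize(exciton_system(c("x", "y"), c(1.9, 1.9),
                                    matrix(c(0, v, v, 0), 2, 2)))
  expect_equal(diff(std$energies), 2 * v, tolerance = 1e-12)
  expect_equal(std$participation_ratios, c(2, 2), tolerance = 1e-9)
})

test_that("coupling magnitude widens the dimer spectrum monotonically", {
  e <- c(1.93, 1.90)
  spread <- vapply(seq(0, 0.03, by = 0.005), function(v) {
    st <- diagonalize(exciton_system(c("x", "y"), e,
                                     matrix(c(0, v, v, 0), 2, 2)))
    diff(range(st$energies))
  }, numeric(1))
  expect_true(all(diff(spread) >= -1e-12))
})

test_that("oscillator strengths follow the prefactor and the dipole sum rule", {
  # single pigment at the 674 nm band energy
  mono <- exciton_system("x", 1.840, matrix(0, 1, 1))
  st <- diagonalize(mono)
  f <- oscillator_strengths(st, matrix(c(4, 0, 0), 1, 3))
  expect_equal(f, 0.1117, tolerance = 1e-2)
  expect_equal(f, 4.702e-7 * (1.840 * 8065.544) * 16, tolerance = 1e-10)

  # symmetric dimer with antiparallel dipoles: the antisymmetric state is dark
  v <- 0.01
  sys <- exciton_system(c("x", "y"), c(1.9, 1.9), matrix(c(0, v, v, 0), 2, 2))
  st <- diagonalize(sys)
  mu <- rbind(c(4, 0, 0), c(-4, 0, 0))
  f <- oscillator_strengths(st, mu)
  expect_equal(sum(f < 1e-4), 1)

  # sum rule: sum_k |mu_k|^2 equals sum_i mu_i^2 for any system
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    e <- runif(n, 1.6, 2.1)
    V <- matrix(runif(n * n, -0.02, 0.02), n, n)
    V <- (V + t(V)) / 2; diag(V) <- 0
    sys <- exciton_system(paste0("s", 1:n), e, V)
    st <- diagonalize(sys)
    mu <- matrix(rnorm(n * 3), n, 3) * runif(n, 2, 5)
    f <- oscillator_strengths(st, mu)
    mu2_exc <- f / (4.702e-7 * st$energies * 8065.544)
    expect_equal(sum(mu2_exc), sum(rowSums(mu^2)), tolerance = 1e-8)
    expect_true(all(f >= 0))
    expect_true(all(st$participation_ratios >= 1 - 1e-9 &
                    st$participation_ratios <= n + 1e-9))
  }
})

test_that("site_energy_gap is signed, supports the pair alias, and validates sites", {
  fx <- psii_fixtures()
  expect_equal(site_energy_gap(fx$systems$chl_d_at_chl_d1, "P_D1/P_D2", "Chl_D1"),
               1.936 - 1.904, tolerance = 1e-12)
  expect_equal(site_energy_gap(fx$systems$chl_f_at_chl_d1, "P_D1/P_D2", "Chl_D1"),
               1.943 - 1.897, tolerance = 1e-12)
  expect_equal(site_energy_gap(fx$systems$wl, "Chl_D1", "Chl_D1"), 0)
  expect_equal(site_energy_gap(fx$systems$wl, "Chl_D1", "P_D1/P_D2"),
               -site_energy_gap(fx$systems$wl, "P_D1/P_D2", "Chl_D1"))
  expect_error(site_energy_gap(fx$systems$wl, "Pheo_D1", "Chl_D1"), "unknown site")
})

test_that("fixture systems carry the tabulated parameters", {
  fx <- psii_fixtures()
  expect_equal(unname(fx$systems$wl$site_energies["Chl_D1"]), 1.993)
  expect_equal(unname(fx$systems$chl_d_at_p_d2$site_energies["P_D1"]), 1.867)
  expect_equal(ev_to_cm1(fx$systems$wl$couplings["P_D1", "P_D2"]), 77,
               tolerance = 1e-9)
  expect_equal(fx$redox_shifts$chl_f$delta_e_ox, 198)
})
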