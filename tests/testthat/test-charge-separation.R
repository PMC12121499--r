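test_that("ct_state_energy books oxidation-potential shifts as stabilization", {
  fx <- psii_fixtures()
  e_d <- ct_state_energy(1.715, fx$redox_shifts$chl_d)
  expect_equal(as.numeric(e_d), 1.570, tolerance = 1e-12)
  expect_match(attr(e_d, "sign_convention"), "stabilization")

  # zero shift leaves the reference unchanged
  expect_equal(as.numeric(ct_state_energy(1.715, redox_shift("Chl_D1", "chl_a", 0))),
               1.715)
  # the Chl f shift gives the deeper radical pair
  expect_equal(as.numeric(ct_state_energy(1.715, fx$redox_shifts$chl_f)),
               1.517, tolerance = 1e-12)
  expect_error(redox_shift("Chl_D1", "chl_d", 1200), "1000 mV")
})

test_that("marcus_rate matches an independent evaluation and its limits", {
  # independent arithmetic of the nonadiabatic closed form
  kt <- kT_298
  k_oracle <- (2 * pi / 6.58212e-16) * 0.01^2 / sqrt(4 * pi * 0.7 * kt) *
    exp(-(-0.15 + 0.7)^2 / (4 * 0.7 * kt))
  expect_equal(marcus_rate(-0.15, 0.7, 0.01, 298.15), k_oracle,
               tolerance = 1e-12)
  expect_equal(marcus_rate(-0.15, 0.7, 0.01, 298.15), 3.0e10, tolerance = 0.03)

  # activationless point: exponential factor exactly 1
  lam <- 0.6
  expect_equal(marcus_rate(-lam, lam, 0.005),
               (2 * pi / 6.58212e-16) * 0.005^2 / sqrt(4 * pi * lam * kt),
               tolerance = 1e-12)
  expect_equal(marcus_rate(-0.2, 0.7, 0), 0)
  # inverted region: more negative driving force than -lambda slows the rate
  expect_lt(marcus_rate(-1.4, 0.7, 0.01), marcus_rate(-0.7, 0.7, 0.01))
})

test_that("detailed balance fixes the backward rate ratio", {
  expect_equal(detailed_balance_backward(5e9, 0), 5e9)
  expect_equal(detailed_balance_backward(1, -0.15) / 1,
               exp(-0.15 / 0.025693), tolerance = 1e-4)
  expect_equal(detailed_balance_backward(1, -0.15), 2.92e-3, tolerance = 0.01)
  expect_equal(detailed_balance_backward(1e10, -3), 1e10 * exp(-3 / kT_298),
               tolerance = 1e-12)
})

test_that("the default networks are well-formed chains over the level scheme", {
  net <- build_default_network("FRL_chl_d")
  expect_length(net$labels, 5)
  expect_equal(max(abs(colSums(net$generator))), 0,
               tolerance = 1e-9 * max(abs(net$generator)))
  e <- vapply(net$states, function(s) s$energy, numeric(1))
  expect_equal(unname(e), c(1.72, 1.57, 1.45, 1.35, 1.25))
  expect_true(all(diff(e) < 0))  # every forward step is downhill
  expect_equal(unname(net$initial_populations), c(1, 0, 0, 0, 0))

  wl <- build_default_network("WL")
  e_wl <- vapply(wl$states, function(s) s$energy, numeric(1))
  expect_equal(unname(e_wl[1:2]), c(1.82, 1.715))
  expect_equal(unname(e_wl[3:5]), unname(e[3:5]))
  expect_error(build_default_network("nope"))
})

test_that("propagation matches closed forms and conserves population", {
  # irreversible two-state A -> B
  k <- 2.31e3
  net <- chain_network(c("A", "B"), c(1.0, 0.5), k, reversible = FALSE)
  tt <- default_time_grid(1e-7, 1e-2, 120)
  res <- propagate(net, tt)
  expect_equal(res$populations[, "B"], 1 - exp(-k * tt), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rowSums(res$populations), rep(1, length(tt)), tolerance = 1e-6)

  # closed reversible two-state network equilibrates to the Boltzmann ratio
  dE <- 0.05
  net2 <- chain_network(c("up", "dn"), c(1.0, 1.0 - dE), 1e9)
  res2 <- propagate(net2, default_time_grid(1e-12, 1e-4, 100))
  p_end <- res2$populations[nrow(res2$populations), ]
  expect_equal(unname(p_end["up"] / p_end["dn"]), exp(-dE / kT_298),
               tolerance = 1e-6)
  expect_equal(unname(p_end), boltzmann_distribution(c(1.0, 1.0 - dE)),
               tolerance = 1e-6, ignore_attr = TRUE)

  # default network: conservation and non-negativity across 12 decades
  res3 <- propagate(build_default_network("FRL_chl_d"))
  expect_true(all(res3$populations >= -1e-9))
  expect_equal(rowSums(res3$populations), rep(1, nrow(res3$populations)),
               tolerance = 1e-6)

  bad <- build_default_network("FRL_chl_d")
  bad$generator[2, 1] <- Inf
  expect_error(propagate(bad), "non-finite")
})

test_that("detailed-balance ladders reach the Boltzmann stationary distribution", {
  set.seed(31)
  for (n in 3:5) {
    e <- sort(runif(n, 1.0, 1.4), decreasing = TRUE)
    rates <- 10^runif(n - 1, 8, 10)
    net <- chain_network(paste0("L", 1:n), e, rates)
    res <- propagate(net, default_time_grid(1e-12, 1e-2, 80))
    p_end <- res$populations[nrow(res$populations), ]
    expect_equal(unname(p_end), boltzmann_distribution(e), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("halftimes: closed form, rate-limiting limit, and monotonicity", {
  k <- 2.31e3
  net <- chain_network(c("A", "B"), c(1.0, 0.5), k, reversible = FALSE)
  res <- propagate(net, default_time_grid(1e-7, 1e-1, 300))
  expect_equal(halftime(res, "B", "formation"), log(2) / k, tolerance = 0.005)

  # the precursor A decays with the same halftime
  expect_equal(halftime(res, "A", "decay"), log(2) / k, tolerance = 0.005)

  # rate-limiting step: slowest rate >= 100x slower than the rest
  net4 <- chain_network(paste0("S", 1:4), c(1.8, 1.6, 1.4, 1.2),
                        c(1e9, 1e4, 1e8), reversible = FALSE)
  res4 <- propagate(net4, default_time_grid(1e-12, 1e-1, 300))
  expect_equal(halftime(res4, "S4", "formation"), log(2) / 1e4,
               tolerance = 0.05)

  # slowing any single forward rate never speeds up final-state formation
  base_rates <- c(1e10, 1e7, 1e5)
  t_base <- halftime(propagate(chain_network(paste0("S", 1:4),
                                             c(1.8, 1.6, 1.4, 1.2),
                                             base_rates, reversible = FALSE),
                               default_time_grid(1e-13, 1e-1, 300)),
                     "S4", "formation")
  for (i in 1:3) {
    slower <- base_rates; slower[i] <- slower[i] / 10
    t_slow <- halftime(propagate(chain_network(paste0("S", 1:4),
                                               c(1.8, 1.6, 1.4, 1.2),
                                               slower, reversible = FALSE),
                                 default_time_grid(1e-13, 1e-1, 300)),
                       "S4", "formation")
    expect_gte(t_slow, t_base * (1 - 1e-6))
  }

  expect_error(halftime(res, "Z", "formation"), "unknown state")
  # an unreachable state is reported as not populated
  net0 <- chain_network(c("A", "B", "C"), c(1.5, 1.0, 0.5), c(1e3, 0),
                        reversible = FALSE)
  res0 <- propagate(net0, default_time_grid(1e-6, 1e-2, 50))
  expect_error(halftime(res0, "C", "formation"), "not populated")
})

test_that("single-exponential fit to propagated two-state data recovers the rate", {
  k <- 5.7e4
  net <- chain_network(c("A", "B"), c(1.0, 0.6), k, reversible = FALSE)
  tt <- seq(1e-6, 8e-5, length.out = 60)
  res <- propagate(net, tt)
  # P_B(t) = 1 - exp(-k t), so a log-linear fit recovers k directly
  fit <- stats::lm(log(1 - res$populations[, "B"]) ~ tt + 0)
  expect_equal(-unname(stats::coef(fit)[1]), k, tolerance = 0.01)
})

test_that("the default far-red cascade reproduces the calibrated halftimes", {
  res <- propagate(build_default_network("FRL_chl_d"))
  t_rp2 <- halftime(res, "PD1PD2+ QA-", "formation")
  expect_equal(t_rp2 * 1e9, 0.2, tolerance = 0.05)
  t_final <- halftime(res, "Mn_ox QB-", "formation")
  expect_equal(t_final, 3.0e-4, tolerance = 0.05)
})
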