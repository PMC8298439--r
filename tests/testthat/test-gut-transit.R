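test_that("gastric emptying curve halves at t_half for both meal types", {
  expect_equal(gastric_fraction_remaining(0), 1.0)
  expect_equal(gastric_fraction_remaining(43, beta = 1.12, t_half = 43), 0.5)
  expect_equal(gastric_fraction_remaining(110, beta = 1.81, t_half = 110), 0.5)
  t <- seq(0, 360, by = 5)
  expect_true(all(diff(gastric_fraction_remaining(t)) < 0))
  expect_error(gastric_fraction_remaining(-1), class = "phesim_invalid_input")
})

test_that("emptying hazard reproduces the power-exponential curve", {
  # beta = 1 reduces to first-order emptying
  expect_equal(gastric_emptying_hazard(c(1, 50, 200), beta = 1, t_half = 43),
               rep(log(2) / 43, 3))
  expect_equal(gastric_emptying_hazard(0, beta = 1.12), 0)
  # solving dX/dt = -k(t) X must track f(t): the printed emptying terms are
  # only dimensionally a rate under this hazard reading
  rhs <- function(t, y, p) list(-gastric_emptying_hazard(t, 1.12, 43) * y)
  out <- deSolve::ode(c(x = 1), times = c(0, 10, 43, 120), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, "x"],
               gastric_fraction_remaining(c(0, 10, 43, 120), 1.12, 43),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("gastric pH decays from the post-meal value to the acidic floor", {
  hp <- gut_params("human")
  expect_equal(gastric_ph(0, hp), 6.0)
  expect_equal(gastric_ph(1e7, hp), 1.71, tolerance = 1e-9)
  expect_equal(gastric_ph(log(2) / hp$k_ph, hp), (6.0 + 1.71) / 2)
  t <- seq(0, 360, 5)
  expect_true(all(diff(gastric_ph(t, hp)) < 0))
  expect_true(all(gastric_ph(t, hp) >= hp$ph_min))
})

test_that("species registries carry their physiology", {
  hp <- gut_params("human")
  np <- gut_params("nhp")
  expect_equal(hp$t_half, 43)
  expect_equal(np$t_half, 24.5)
  expect_equal(np$ph_min, 1.97)
  expect_equal(np$phe_st0, 1513.41)
  expect_equal(gut_params("human", t_half = 110, beta = 1.81)$t_half, 110)
  expect_error(gut_params("dog"), class = "phesim_invalid_input")
  expect_error(gut_params("human", bogus = 1), class = "phesim_invalid_input")
})

test_that("meal Phe in grams sets the initial stomach amount", {
  sim <- simulate_gi_dose(0, meal_phe_g = 2.0)
  expect_equal(sim$series$phe_st[1], 12108, tolerance = 1e-4) # 2 g / 165.19 g/mol
  nhp <- simulate_gi_dose(0, meal_phe_g = 0.25, params = gut_params("nhp"))
  expect_equal(nhp$series$phe_st[1], 1513.41, tolerance = 1e-4)
})

test_that("no dose means no TCA and full mass accounting", {
  sim <- simulate_gi_dose(0, meal_phe_g = 2.0)
  expect_equal(sim$predicted_ha_umol, 0)
  s <- sim$series
  expect_true(all(abs(s$tca_st) < 1e-9 & abs(s$tca_si) < 1e-9))
  total0 <- s$phe_st[1] + s$phe_si[1]
  total <- s$phe_st + s$phe_si + s$tca_st + s$tca_si +
    s$phe_absorbed + s$tca_absorbed
  expect_lt(max(abs(total - total0)), 1e-6 * total0)
  # by 6 h nearly everything has emptied and been absorbed
  expect_gt(tail(s$phe_absorbed, 1), 0.95 * total0)
})

test_that("cells are conserved between compartments and mass balances", {
  sim <- simulate_gi_dose(1e11, meal_phe_g = 2.0)
  s <- sim$series
  expect_lt(max(abs(s$cells_st + s$cells_si - 1e11)), 1e-6 * 1e11)
  total0 <- s$phe_st[1] + s$phe_si[1]
  total <- s$phe_st + s$phe_si + s$tca_st + s$tca_si +
    s$phe_absorbed + s$tca_absorbed
  expect_lt(max(abs(total - total0)), 1e-6 * total0)
  expect_true(all(s$phe_absorbed >= 0))
  expect_true(all(diff(s$phe_absorbed) >= 0))
})

test_that("absorption switch-off keeps Phe in the lumen", {
  sim <- simulate_gi_dose(0, meal_phe_g = 2.0, params = gut_params("human", lam = 0))
  expect_true(all(sim$series$phe_absorbed == 0))
  expect_true(all(sim$series$tca_absorbed == 0))
})

test_that("GI simulation agrees with a fixed-step Euler oracle", {
  sim <- simulate_gi_dose(1e11, meal_phe_g = 2.0)
  fin <- sim$series[nrow(sim$series), ]
  oracle <- euler_gi(1e11, 2.0 / 165.19 * 1e6, t_end = 360, dt = 0.01)
  for (nm in c("phe_st", "tca_st", "phe_si", "tca_si")) {
    denom <- max(abs(oracle[[nm]]), 1e-3 * 12108)
    expect_lt(abs(fin[[nm]] - oracle[[nm]]) / denom, 5e-3)
  }
  expect_equal(fin$phe_absorbed, oracle[["phe_abs"]], tolerance = 5e-3,
               ignore_attr = TRUE)
  expect_equal(fin$tca_absorbed, oracle[["tca_abs"]], tolerance = 5e-3,
               ignore_attr = TRUE)
})

test_that("predicted HA rises with dose and saturates below meal Phe", {
  doses <- c(0, 1e10, 1e11, 5e11, 2e12)
  dr <- ha_dose_response(doses, meal_phe_g = 2.0, with_ci = TRUE)
  expect_equal(dr$ha_umol[1], 0)
  expect_equal(dr$ha_lo[1], 0)
  expect_true(all(diff(dr$ha_umol) > 0))
  expect_true(all(dr$ha_lo <= dr$ha_umol + 1e-9 & dr$ha_umol <= dr$ha_hi + 1e-9))
  # sub-saturation linearity: doubling a small dose ~doubles HA
  low <- ha_dose_response(c(5e9, 1e10), meal_phe_g = 2.0, with_ci = FALSE)
  expect_equal(low$ha_umol[2] / low$ha_umol[1], 2, tolerance = 0.05)
  # bounded by total luminal Phe at any dose
  expect_true(all(dr$ha_hi < 12108 + 30.2))
})

test_that("late-time stomach PAL activity is shut off by gastric acid", {
  # once gastric pH falls below 2.8 the pH multiplier clamps to zero, so
  # stomach TCA production stops; any later TCA gain is SI inflow only
  hp <- gut_params("human")
  t_cut <- log((hp$ph0 - hp$ph_min) / (2.8 - hp$ph_min)) / hp$k_ph
  expect_lt(gastric_ph(t_cut + 1, hp), 2.8)
  expect_equal(ki_ph(gastric_ph(t_cut + 1, hp)), 0)
})

test_that("glance and tidy expose the GI result", {
  sim <- simulate_gi_dose(1e11, meal_phe_g = 2.0)
  g <- glance(sim)
  expect_equal(g$predicted_ha_umol, sim$phe_consumed_umol)
  expect_equal(g$predicted_ha_mg, sim$predicted_ha_umol * 179.17 / 1000)
  expect_named(tidy(sim), c("t_min", "cells_st", "cells_si", "phe_st",
                            "tca_st", "phe_si", "tca_si", "phe_absorbed",
                            "tca_absorbed", "gastric_ph"))
})
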