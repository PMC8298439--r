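test_that("elimination rate laws evaluate to their closed forms", {
  p <- blood_params()
  # substrate-activation PAH form at a healthy fasting concentration
  expect_equal(pah_rate(0.065, f_pah = 1),
               0.9 / (1 + 0.51 / 0.065 + 0.51 * 0.54 / 0.065^2),
               tolerance = 1e-12)
  expect_equal(pah_rate(0.065, f_pah = 1), 0.01216, tolerance = 1e-3)
  expect_equal(pah_rate(2, f_pah = 0), 0)
  expect_equal(pah_rate(0, f_pah = 1), 0)
  expect_equal(pah_rate(1e6, f_pah = 1), 0.9, tolerance = 1e-3) # saturation
  expect_equal(pah_rate(1, f_pah = 0.5), 0.5 * pah_rate(1, f_pah = 1))

  expect_equal(trans_rate(1.18), 0.063 / (1 + 1.37 / 1.18), tolerance = 1e-12)
  expect_equal(trans_rate(1.18), 0.02915, tolerance = 1e-3)
  expect_equal(trans_rate(p$km_trans), p$vmax_trans / 2)
  expect_equal(trans_rate(0), 0)

  expect_equal(renal_rate(1.18), 1.18 * 5.696e-4 * 0.5, tolerance = 1e-12)
  expect_equal(renal_rate(2 * 1.18), 2 * renal_rate(1.18))
  expect_equal(renal_rate(0), 0)
  expect_error(pah_rate(-1), class = "phesim_invalid_input")
})

test_that("gut-to-plasma conversion follows the dimensional identity", {
  p <- blood_params()
  expect_equal(gut_to_plasma_factor(p), 1 / (165.19 * 0.5 * 70),
               tolerance = 1e-12)
  expect_equal(gut_to_plasma_factor(p), 1.7297e-4, tolerance = 1e-4)
  expect_equal(gut_to_plasma_factor(blood_params(weight = 140)),
               gut_to_plasma_factor(p) / 2)
  # a 1000 mg bolus delivers 0.1730 mmol/L cumulative plasma input
  expect_equal(1000 * gut_to_plasma_factor(p), 0.17297, tolerance = 1e-4)
})

test_that("the gut compartment empties as an exact exponential", {
  sched <- meal_schedule(2.5, times_hr = 0) # single daily meal at t = 0
  sim <- simulate_blood(days = 1, schedule = sched, f_pah = 0,
                        rtol = 1e-12, atol = 1e-14)
  s <- sim$series[sim$series$t_hr <= 23.9, ] # before the readout extension
  expect_equal(s$gut_mg, 2500 * exp(-0.25 * s$t_hr), tolerance = 1e-9)
})

test_that("meal-free simulation relaxes to the fasting equilibrium root", {
  eq <- fasting_equilibrium(f_pah = 0)
  sim <- simulate_blood(days = 60, schedule = meal_schedule(0), f_pah = 0)
  expect_equal(tail(sim$series$phe_mmol_l, 1), eq, tolerance = 1e-3)
  # the root actually balances production against elimination
  expect_equal(blood_params()$v_npd,
               trans_rate(eq) + renal_rate(eq), tolerance = 1e-9)
  # healthy equilibrium sits far lower
  expect_lt(fasting_equilibrium(1), 0.1)
})

test_that("full removal is equivalent to a zero-Phe diet", {
  a <- simulate_blood(days = 20,
                      schedule = meal_schedule(2.5, removal_fraction = 1),
                      f_pah = 0)
  b <- simulate_blood(days = 20, schedule = meal_schedule(0), f_pah = 0)
  expect_equal(a$series$phe_mmol_l, b$series$phe_mmol_l, tolerance = 1e-12)
  expect_equal(fasting_phe(a), fasting_phe(b))
})

test_that("the trajectory settles into a 24-h periodic orbit", {
  sim <- simulate_blood(days = 60, f_pah = 0)
  s <- sim$series
  f_final <- s$phe_mmol_l[s$t_hr == sim$t_fasting_hr]
  f_prev <- s$phe_mmol_l[s$t_hr == sim$t_fasting_hr - 24]
  expect_equal(f_final, f_prev, tolerance = 1e-3)
  # intra-day variation persists (meals drive the orbit)
  last_day <- s[s$t_hr >= max(s$t_hr) - 24, ]
  expect_gt(max(last_day$phe_mmol_l) - min(last_day$phe_mmol_l), 0.05)
})

test_that("fasting Phe falls with dietary removal and with PAH activity", {
  scan <- diet_reduction_scan(c(0, 0.25, 0.5, 0.75), days = 40)
  expect_equal(scan$pct_lowering[1], 0)
  expect_true(all(diff(scan$fasting_phe_umol_l) < 0))
  expect_true(all(diff(scan$pct_lowering) > 0))
  f0 <- fasting_phe(simulate_blood(days = 40, f_pah = 0, phe0 = 1.18))
  f05 <- fasting_phe(simulate_blood(days = 40, f_pah = 0.5, phe0 = 1.18))
  f1 <- fasting_phe(simulate_blood(days = 40, f_pah = 1, phe0 = 1.18))
  expect_true(f0 > f05 && f05 > f1)
})

test_that("average fluxes balance over a steady-state day", {
  sim <- simulate_blood(days = 60, f_pah = 0)
  s <- sim$series
  d <- s[s$t_hr >= max(s$t_hr) - 24, ]
  p <- sim$params
  elim <- phesim:::trapz(d$t_hr, trans_rate(d$phe_mmol_l, p) +
                           renal_rate(d$phe_mmol_l, p))
  input <- 2500 * gut_to_plasma_factor(p) + 24 * p$v_npd
  expect_equal(elim, input, tolerance = 5e-3)
})

test_that("inversion of the removal scan is self-consistent", {
  # modest horizon keeps the round trip fast; consistency is what matters
  mg <- required_consumption_for_lowering(20, days = 40)
  sched <- meal_schedule(2.5, removal_mg_per_meal = mg / 3)
  f <- fasting_phe(simulate_blood(days = 40, schedule = sched, f_pah = 0))
  base <- fasting_phe(simulate_blood(days = 40, f_pah = 0))
  expect_equal(100 * (1 - f / base), 20, tolerance = 0.5 / 20)
  expect_equal(required_consumption_for_lowering(0), 0)
  expect_error(required_consumption_for_lowering(90, days = 30),
               class = "phesim_domain_error")
})

test_that("elimination attribution fractions are exact and normalized", {
  sim <- simulate_blood(days = 40, f_pah = 0)
  att <- elimination_attribution(sim)
  expect_equal(sum(att$fraction), 1, tolerance = 1e-9)
  expect_equal(att$fraction[att$pathway == "pah"], 0)
  expect_gt(att$fraction[att$pathway == "trans"], 0.95)
  att1 <- elimination_attribution(simulate_blood(days = 40, f_pah = 1))
  expect_gt(att1$fraction[att1$pathway == "pah"], 0.5)
})

test_that("meal schedules validate and apply removal correctly", {
  expect_error(meal_schedule(-1), class = "phesim_invalid_input")
  expect_error(meal_schedule(2.5, times_hr = c(0, 25)),
               class = "phesim_invalid_input")
  expect_error(meal_schedule(2.5, fractions = c(0.5, 0.2)),
               class = "phesim_invalid_input")
  expect_error(meal_schedule(2.5, removal_fraction = 1.2),
               class = "phesim_invalid_input")
  # absolute removal is clipped at the meal content
  sched <- meal_schedule(2.5, removal_mg_per_meal = 5000)
  expect_equal(phesim:::meal_boluses_mg(sched), rep(0, 3))
})
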