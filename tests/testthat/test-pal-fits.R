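test_that("noiseless Michaelis-Menten data are recovered exactly", {
  d <- simulate_rate_data("mm_rates", noise_cv = 0)
  fit <- fit_michaelis_menten(d)
  expect_equal(unname(fit$estimates[["km"]]), 0.0184, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["vmax"]]), 0.0162, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  td <- tidy(fit)
  expect_setequal(td$term, c("km", "vmax"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("noiseless pH line and TCA decay are recovered exactly", {
  dph <- simulate_rate_data("ph_activity", design_points = c(4, 5, 6, 7),
                            noise_cv = 0)
  fph <- fit_ph_linear(dph)
  expect_equal(unname(fph$estimates), c(0.25, -0.7), tolerance = 1e-9)
  expect_equal(fph$r_squared, 1.0, tolerance = 1e-9)

  dtca <- simulate_rate_data("tca_inhibition", noise_cv = 0)
  ftca <- fit_tca_exponential(dtca)
  expect_equal(unname(ftca$estimates[c("amp", "rate", "floor")]),
               c(0.67, 0.53, 0.33), tolerance = 1e-6)
  expect_equal(ftca$r_squared, 1.0, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_michaelis_menten(data.frame(x = c(1, 1, 1), y = c(1, 2, 3))),
               class = "phesim_invalid_input")
  expect_error(fit_michaelis_menten(data.frame(x = 1, y = 1)),
               class = "phesim_invalid_input")
  expect_error(fit_tca_exponential(data.frame(x = c(1, 2, 4, 8), y = 1:4)),
               class = "phesim_invalid_input") # no zero-TCA condition
  # constant response: slope 0, undefined R^2, warning raised
  expect_warning(
    f <- fit_ph_linear(data.frame(x = c(4, 5, 6, 7), y = rep(0.5, 4))),
    class = "phesim_degenerate_fit"
  )
  expect_equal(unname(f$estimates[["slope"]]), 0)
  expect_true(is.na(f$r_squared))
  # flat decay data: rate ~ 0 (warned) or non-convergence
  flat <- data.frame(x = c(0, 0.5, 1, 2, 4, 8), y = rep(1, 6))
  res <- tryCatch(
    withCallingHandlers(
      fit_tca_exponential(flat),
      warning = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) e
  )
  if (inherits(res, "pal_fit")) {
    expect_lt(unname(res$estimates[["rate"]]), 1e-3)
  } else {
    expect_s3_class(res, "phesim_fit_error")
  }
})

test_that("Monte-Carlo recovery: fitted 95% CIs cover the generating truth", {
  # the characterization design (0.3125-40 umol/mL) sits entirely above Km,
  # so Km point estimates scatter widely there; the asymptotic intervals
  # must still own up to that uncertainty and cover the truth
  n_seeds <- 200
  cover_km <- cover_vmax <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    d <- simulate_rate_data("mm_rates", noise_cv = 0.15, seed = s)
    td <- tidy(fit_michaelis_menten(d))
    km_row <- td[td$term == "km", ]
    vmax_row <- td[td$term == "vmax", ]
    cover_km[s] <- km_row$conf.low <= 0.0184 && 0.0184 <= km_row$conf.high
    cover_vmax[s] <- vmax_row$conf.low <= 0.0162 && 0.0162 <= vmax_row$conf.high
  }
  expect_gte(mean(cover_km & cover_vmax), 0.90)
})

test_that("Km point estimates recover under a design spanning half-saturation", {
  # with design points below and above Km (the fitter's stated precondition)
  # the point estimate itself is reliable to within a factor of 2
  design <- c(0.005, 0.01, 0.02, 0.04, 0.08, 0.3125, 1.25, 5, 20, 40)
  km_2x <- vapply(1:200, function(s) {
    d <- simulate_rate_data("mm_rates", design_points = design,
                            noise_cv = 0.15, seed = s)
    km <- unname(fit_michaelis_menten(d)$estimates[["km"]])
    km > 0.0184 / 2 && km < 0.0184 * 2
  }, logical(1))
  expect_gte(mean(km_2x), 0.95)
})

test_that("Monte-Carlo recovery of the pH slope and TCA floor", {
  slopes <- vapply(1:50, function(s) {
    d <- simulate_rate_data("ph_activity", noise_cv = 0.15, seed = s)
    unname(fit_ph_linear(d)$estimates[["slope"]])
  }, numeric(1))
  expect_lt(median(abs(slopes - 0.25) / 0.25), 0.20)

  d1 <- simulate_rate_data("tca_inhibition", noise_cv = 0.1, seed = 1)
  f1 <- fit_tca_exponential(d1)
  expect_lt(abs(unname(f1$estimates[["floor"]]) - 0.33), 0.05)
})

test_that("fitted parameters flow back into a pal_params object", {
  mm <- fit_michaelis_menten(simulate_rate_data("mm_rates", noise_cv = 0))
  ph <- fit_ph_linear(simulate_rate_data("ph_activity", noise_cv = 0))
  tca <- fit_tca_exponential(simulate_rate_data("tca_inhibition", noise_cv = 0))
  kin <- pal_params_from_fits(mm, ph, tca)
  expect_s3_class(kin, "pal_params")
  expect_equal(kin$km, 0.0184, tolerance = 1e-6)
  expect_equal(kin$vmax, 0.0162, tolerance = 1e-6)
  expect_equal(kin$ki_ph_slope, 0.25, tolerance = 1e-6)
  expect_equal(kin$ki_tca_floor, 0.33, tolerance = 1e-4)
  expect_true(kin$km_lo <= kin$km && kin$km <= kin$km_hi)
})

test_that("glance reports the goodness of fit", {
  d <- simulate_rate_data("mm_rates", noise_cv = 0.15, seed = 7)
  g <- glance(fit_michaelis_menten(d))
  expect_equal(g$nobs, nrow(d))
  expect_true(g$r.squared > 0 && g$r.squared <= 1)
})
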