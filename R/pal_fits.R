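# Nonlinear fitting of the PAL kinetic coefficients from in vitro rate data.
#
# All three fitters share the same machinery: trust-region least squares
# (minpack.lm) with a small multi-start around method-of-moments initial
# guesses, analytic R^2, and asymptotic 95% confidence intervals from the
# Jacobian. Results are returned as a `pal_fit` object with broom-style
# tidy()/glance() methods.

validate_rate_data <- function(data, min_distinct = 3L) {
  if (!is.data.frame(data) || !all(c("x", "y") %in% names(data))) {
    abort_input("`data` must be a data frame with columns `x` and `y`.")
  }
  if (nrow(data) < min_distinct) {
    abort_input(sprintf("`data` must have at least %d rows.", min_distinct))
  }
  check_finite(data$x, "data$x")
  check_finite(data$y, "data$y")
  if (length(unique(data$x)) < min_distinct) {
    abort_input(sprintf(
      "`data$x` must contain at least %d distinct values.", min_distinct
    ))
  }
  invisible(data)
}

new_pal_fit <- function(model, estimates, se, df_resid, fitted, data,
                        warning = NULL) {
  resid <- data$y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((data$y - mean(data$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tcrit <- qt(0.975, df = max(df_resid, 1))
  structure(
    list(
      model = model,
      estimates = estimates,
      std_errors = se,
      conf_low = estimates - tcrit * se,
      conf_high = estimates + tcrit * se,
      r_squared = r2,
      sigma = sqrt(ss_res / max(df_resid, 1)),
      df_residual = df_resid,
      nobs = nrow(data),
      data = as_tibble(data),
      fitted = fitted,
      warning = warning
    ),
    class = "pal_fit"
  )
}

# Run nlsLM from several starts, keep the converged fit with least deviance.
nls_multistart <- function(formula, data, starts, lower, what) {
  fits <- list()
  msgs <- character()
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) conditionMessage(e)
    )
    if (inherits(f, "nls")) fits[[length(fits) + 1L]] <- f else msgs <- c(msgs, f)
  }
  if (!length(fits)) {
    abort_fit(sprintf(
      "%s did not converge from any start. Solver messages: %s",
      what, paste(unique(msgs), collapse = "; ")
    ))
  }
  fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
}

#' Fit Michaelis-Menten kinetics to concentration-rate data
#'
#' Nonlinear least squares of `rate = vmax * x / (km + x)` to whole-cell rate
#' measurements across substrate concentrations, as used to estimate the
#' strain's `km`/`vmax` from in vitro TCA production rates.
#'
#' @param data Data frame with columns `x` (Phe concentration, umol/mL) and
#'   `y` (rate, umol/(min x 1e9 CFU)); an optional `replicate` column is
#'   carried along. Needs at least 3 distinct concentrations spanning the
#'   half-saturation region.
#' @return A `pal_fit` object with terms `km` and `vmax`; see [tidy.pal_fit()]
#'   and [glance.pal_fit()].
#' @examples
#' d <- simulate_rate_data("mm_rates", noise_cv = 0)
#' glance(fit_michaelis_menten(d))$r.squared # 1 on noiseless data
#' @export
fit_michaelis_menten <- function(data) {
  validate_rate_data(data, 3L)
  check_nonneg(data$x, "data$x")
  vmax0 <- max(data$y)
  if (vmax0 <= 0) abort_fit("All rates are <= 0; cannot fit a saturation curve.")
  # method-of-moments Km guess: x nearest half the apparent plateau
  km0 <- data$x[which.min(abs(data$y - vmax0 / 2))]
  km0 <- max(km0, min(data$x[data$x > 0]) / 10)
  starts <- lapply(c(0.3, 1, 3), function(m) list(km = km0 * m, vmax = vmax0))
  fit <- nls_multistart(y ~ vmax * x / (km + x), data, starts,
                        lower = c(km = 0, vmax = 0), what = "fit_michaelis_menten")
  s <- summary(fit)
  est <- coef(fit)[c("km", "vmax")]
  se <- s$coefficients[c("km", "vmax"), "Std. Error"]
  new_pal_fit("michaelis_menten", est, se, s$df[2], predict(fit), data)
}

#' Fit the linear pH-activity relationship
#'
#' Ordinary least squares of relative PAL activity against pH. The slope and
#' intercept populate the pH-inhibition coefficients of [pal_params()]
#' (the model clamps the line to \[0, 1\] when it is used as a multiplier).
#'
#' @param data Data frame with columns `x` (pH) and `y` (activity fraction
#'   relative to pH 7). At least 3 distinct pH values.
#' @return A `pal_fit` object with terms `slope` and `intercept`. Constant
#'   responses yield slope 0 with `r.squared` flagged `NA` (and a warning).
#' @examples
#' d <- simulate_rate_data("ph_activity", noise_cv = 0)
#' tidy(fit_ph_linear(d))
#' @export
fit_ph_linear <- function(data) {
  validate_rate_data(data, 3L)
  fit <- lm(y ~ x, data = data)
  # summary.lm warns on exact (noiseless) fits; that's a legitimate input here
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  se <- c(s$coefficients["x", "Std. Error"], s$coefficients["(Intercept)", "Std. Error"])
  wmsg <- NULL
  if (var(data$y) == 0) {
    wmsg <- "Constant response: slope is 0 and R^2 is undefined."
    warn(wmsg, class = "phesim_degenerate_fit")
  }
  out <- new_pal_fit("ph_linear", est, setNames(se, names(est)),
                     fit$df.residual, unname(fitted(fit)), data, warning = wmsg)
  if (!is.null(wmsg)) out$r_squared <- NA_real_
  out
}

#' Fit the exponential TCA product-inhibition curve
#'
#' Least-squares fit of `y = amp * exp(-rate * x) + floor` to relative
#' activity measured across exogenous TCA levels. With activity expressed
#' relative to the zero-TCA condition, `amp + floor` is ~1 by construction.
#'
#' @param data Data frame with columns `x` (TCA, mM) and `y` (relative
#'   activity). At least 4 distinct TCA levels including 0.
#' @return A `pal_fit` object with terms `amp`, `rate` and `floor`. Flat data
#'   resolve to `rate` ~ 0 (or raise a fit error if the solver cannot
#'   converge).
#' @examples
#' d <- simulate_rate_data("tca_inhibition", noise_cv = 0)
#' tidy(fit_tca_exponential(d))
#' @export
fit_tca_exponential <- function(data) {
  validate_rate_data(data, 4L)
  check_nonneg(data$x, "data$x")
  if (!any(data$x == 0)) {
    abort_input("`data$x` must include the zero-TCA condition.")
  }
  y0 <- mean(data$y[data$x == 0])
  c0 <- max(min(data$y), 0)
  a0 <- max(y0 - c0, 1e-3)
  # log-linear decay-rate guess on the floor-subtracted signal
  pos <- data$y - c0 > a0 * 1e-3 & data$x > 0
  k0 <- if (sum(pos) >= 2) {
    k <- -coef(lm(log(data$y[pos] - c0) ~ data$x[pos]))[2]
    if (is.finite(k) && k > 0) unname(k) else 0.5
  } else 0.5
  starts <- lapply(c(0.3, 1, 3), function(m) list(amp = a0, rate = k0 * m, floor = c0))
  fit <- nls_multistart(y ~ amp * exp(-rate * x) + floor, data, starts,
                        lower = c(amp = 0, rate = 0, floor = 0),
                        what = "fit_tca_exponential")
  s <- summary(fit)
  est <- coef(fit)[c("amp", "rate", "floor")]
  se <- s$coefficients[c("amp", "rate", "floor"), "Std. Error"]
  wmsg <- NULL
  if (est[["rate"]] < 1e-6) {
    wmsg <- "No detectable decay: fitted rate is ~0."
    warn(wmsg, class = "phesim_degenerate_fit")
  }
  new_pal_fit("tca_exponential", est, se, s$df[2], predict(fit), data,
              warning = wmsg)
}

#' @export
print.pal_fit <- function(x, ...) {
  cat(sprintf("<pal_fit> %s (n = %d)\n", x$model, x$nobs))
  tb <- tidy(x)
  print(as.data.frame(tb), row.names = FALSE, digits = 4)
  cat(sprintf("R-squared: %s\n",
              ifelse(is.na(x$r_squared), "undefined", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Tidy a PAL kinetics fit
#'
#' @param x A `pal_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high` (asymptotic 95% intervals).
#' @export
tidy.pal_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors),
    conf.low = unname(x$conf_low),
    conf.high = unname(x$conf_high)
  )
}

#' One-row summary of a PAL kinetics fit
#'
#' @param x A `pal_fit` object.
#' @param ... Unused.
#' @return A tibble with `model`, `r.squared`, `sigma`, `df.residual`, `nobs`.
#' @export
glance.pal_fit <- function(x, ...) {
  tibble(
    model = x$model,
    r.squared = x$r_squared,
    sigma = x$sigma,
    df.residual = x$df_residual,
    nobs = x$nobs
  )
}

# Predict from a pal_fit on new x values (used by autoplot and tests).
predict_pal_fit <- function(object, x) {
  e <- as.list(object$estimates)
  switch(object$model,
    michaelis_menten = e$vmax * x / (e$km + x),
    ph_linear = e$slope * x + e$intercept,
    tca_exponential = e$amp * exp(-e$rate * x) + e$floor,
    abort_input(sprintf("Unknown fit model '%s'.", object$model))
  )
}

#' Build PAL kinetic parameters from fitted curves
#'
#' Assembles a [pal_params()] object from a Michaelis-Menten fit and,
#' optionally, pH-line and TCA-decay fits, wiring fitted point estimates and
#' the Michaelis-Menten 95% confidence bounds into the simulator's parameter
#' object.
#'
#' @param mm_fit A `pal_fit` from [fit_michaelis_menten()].
#' @param ph_fit Optional `pal_fit` from [fit_ph_linear()].
#' @param tca_fit Optional `pal_fit` from [fit_tca_exponential()].
#' @return A [pal_params()] object.
#' @export
pal_params_from_fits <- function(mm_fit, ph_fit = NULL, tca_fit = NULL) {
  if (!inherits(mm_fit, "pal_fit") || mm_fit$model != "michaelis_menten") {
    abort_input("`mm_fit` must come from fit_michaelis_menten().")
  }
  defaults <- pal_params()
  e <- as.list(mm_fit$estimates)
  km_ci <- c(max(mm_fit$conf_low[["km"]], e$km * 1e-6), mm_fit$conf_high[["km"]])
  vmax_ci <- c(max(mm_fit$conf_low[["vmax"]], e$vmax * 1e-6), mm_fit$conf_high[["vmax"]])
  ph <- if (!is.null(ph_fit)) as.list(ph_fit$estimates) else
    list(slope = defaults$ki_ph_slope, intercept = defaults$ki_ph_intercept)
  tca <- if (!is.null(tca_fit)) as.list(tca_fit$estimates) else
    list(amp = defaults$ki_tca_amp, rate = defaults$ki_tca_rate,
         floor = defaults$ki_tca_floor)
  pal_params(
    km = e$km, vmax = e$vmax, km_ci = km_ci, vmax_ci = vmax_ci,
    ki_ph_slope = ph$slope, ki_ph_intercept = ph$intercept,
    ki_tca_amp = tca$amp, ki_tca_rate = tca$rate, ki_tca_floor = tca$floor
  )
}
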