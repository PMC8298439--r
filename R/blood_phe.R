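#' Elementary elimination fluxes of the blood Phe model
#'
#' `pah_rate()` is the phenylalanine hydroxylase (PAH) elimination rate with
#' substrate activation,
#' `vmax_pah * f_pah / (1 + km_pah/Phe + km_pah*ka_pah/Phe^2)`, scaled by the
#' residual activity fraction `f_pah` (0 = classical PKU, 1 = healthy).
#' `trans_rate()` is the transaminase Michaelis-Menten rate
#' `vmax_trans / (1 + km_trans/Phe)`. `renal_rate()` is the linear renal
#' elimination `Phe * cl_renal * vd`, implemented exactly as the model
#' composes it. All return 0 at `phe = 0` (the continuous limit).
#'
#' @param phe Plasma Phe concentration, mmol/L. Vectorized.
#' @param f_pah Fraction of healthy PAH activity in \[0, 1\].
#' @param params A [blood_params()] object.
#' @return Elimination rate, (mmol/L)/hr.
#' @examples
#' pah_rate(0.065, f_pah = 1)
#' trans_rate(1.18)
#' @export
pah_rate <- function(phe, f_pah = 1, params = blood_params()) {
  check_nonneg(phe, "phe")
  check_nonneg(f_pah, "f_pah")
  if (any(f_pah > 1)) abort_input("`f_pah` must be in [0, 1].")
  # algebraic rearrangement of vmax*f / (1 + Km/P + Km*Ka/P^2), 0-safe
  params$vmax_pah * f_pah * phe^2 /
    (phe^2 + params$km_pah * phe + params$km_pah * params$ka_pah)
}

#' @rdname pah_rate
#' @export
trans_rate <- function(phe, params = blood_params()) {
  check_nonneg(phe, "phe")
  params$vmax_trans * phe / (params$km_trans + phe)
}

#' @rdname pah_rate
#' @export
renal_rate <- function(phe, params = blood_params()) {
  check_nonneg(phe, "phe")
  phe * params$cl_renal * params$vd
}

#' Gut-to-plasma unit conversion factor
#'
#' Converts gut Phe content (mg) into the plasma concentration increment it
#' delivers on complete absorption: `1 / (mw_phe * vd * weight)` in
#' (mmol/L)/mg.
#'
#' @param params A [blood_params()] object.
#' @return Conversion factor, (mmol/L)/mg.
#' @examples
#' gut_to_plasma_factor() # 1/(165.19 * 0.5 * 70)
#' @export
gut_to_plasma_factor <- function(params = blood_params()) {
  1 / (params$mw_phe * params$vd * params$weight)
}

# RHS of the two-state blood model: y = (phe mmol/L, gut mg), time in hours.
blood_rhs <- function(t, y, parms) {
  p <- parms$params
  phe <- max(y[[1]], 0)
  dphe <- p$ka_gut * y[[2]] * parms$fgp + p$v_npd -
    pah_rate(phe, parms$f_pah, p) - trans_rate(phe, p) - renal_rate(phe, p)
  list(c(phe = dphe, gut = -p$ka_gut * y[[2]]))
}

#' Simulate plasma Phe under a daily meal schedule
#'
#' Integrates the extended blood Phe model over `days` days. Meals enter the
#' gut compartment as instantaneous boluses (net of any luminal removal) at
#' the scheduled times each day and are absorbed into plasma with first-order
#' kinetics; plasma Phe balances absorption and net protein breakdown against
#' PAH, transaminase and renal elimination. With a constant schedule the
#' trajectory converges to a 24-hour periodic orbit (pseudo-steady state)
#' within roughly a week, so long-horizon readouts are independent of the
#' initial condition.
#'
#' The horizon extends past the last day's final meal so that the fasting
#' readout 14 h later (next morning, 8:00 AM anchor) is always on the grid.
#'
#' @param days Number of simulated days (>= 1).
#' @param schedule A [meal_schedule()] object.
#' @param f_pah Fraction of healthy PAH activity in \[0, 1\].
#' @param params A [blood_params()] object.
#' @param phe0 Initial plasma Phe, mmol/L. Default: `params$phe0`
#'   (1.18 mmol/L) for `f_pah < 0.5`, 0.06 mmol/L (physiological baseline)
#'   otherwise.
#' @param dt_out Output grid spacing, hours.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return An object of class `blood_sim`: a list with `series` (tibble of
#'   `t_hr`, `phe_mmol_l`, `gut_mg`), the scenario (`schedule`, `f_pah`,
#'   `params`, `days`) and `t_fasting_hr`, the fasting readout time.
#' @examples
#' sim <- simulate_blood(days = 30, f_pah = 0)
#' fasting_phe(sim)
#' @export
simulate_blood <- function(days = 180,
                           schedule = meal_schedule(),
                           f_pah = 0,
                           params = blood_params(),
                           phe0 = NULL,
                           dt_out = 0.25,
                           rtol = 1e-8, atol = 1e-10) {
  check_pos(days, "days"); check_scalar(days, "days")
  if (days < 1) abort_input("`days` must be >= 1.")
  if (!inherits(schedule, "meal_schedule")) {
    abort_input("`schedule` must be a meal_schedule().")
  }
  if (!inherits(params, "blood_params")) {
    abort_input("`params` must be blood_params().")
  }
  check_nonneg(f_pah, "f_pah"); check_scalar(f_pah, "f_pah")
  if (f_pah > 1) abort_input("`f_pah` must be in [0, 1].")
  phe0 <- phe0 %||% if (f_pah >= 0.5) 0.06 else params$phe0
  check_nonneg(phe0, "phe0")

  boluses <- meal_boluses_mg(schedule)
  meal_t <- as.vector(outer(schedule$times_hr, (seq_len(days) - 1) * 24, "+"))
  meal_v <- rep(boluses, times = days)
  # fasting readout: 14 h after the last day's final meal
  t_fast <- (days - 1) * 24 + max(schedule$times_hr) + 14
  horizon <- max(days * 24, t_fast)

  y0 <- c(phe = phe0, gut = 0)
  # the t = 0 meal (if any) goes into the initial state; later meals are
  # integrator events that add to the gut compartment
  if (any(meal_t == 0)) y0[["gut"]] <- sum(meal_v[meal_t == 0])
  ev_t <- meal_t[meal_t > 0]
  ev_v <- meal_v[meal_t > 0]
  events <- if (length(ev_t)) {
    list(data = data.frame(var = "gut", time = ev_t, value = ev_v,
                           method = "add"))
  } else NULL

  times <- sort(unique(c(seq(0, horizon, by = dt_out), meal_t, t_fast, horizon)))
  out <- integrate_checked(
    y = y0, times = times, func = blood_rhs,
    parms = list(params = params, f_pah = f_pah,
                 fgp = gut_to_plasma_factor(params)),
    what = "simulate_blood", events = events, rtol = rtol, atol = atol
  )
  series <- tibble(
    t_hr = out[, "time"],
    phe_mmol_l = pmax(out[, "phe"], 0),
    gut_mg = pmax(out[, "gut"], 0)
  )
  structure(
    list(series = series, schedule = schedule, f_pah = f_pah, params = params,
         days = days, t_fasting_hr = t_fast),
    class = "blood_sim"
  )
}

#' @export
print.blood_sim <- function(x, ...) {
  cat(sprintf("<blood_sim> %g days, f_pah = %.3g, %.3g g Phe/day\n",
              x$days, x$f_pah, x$schedule$daily_phe_g))
  cat(sprintf("  fasting plasma Phe (14 h post-meal): %.1f umol/L\n",
              fasting_phe(x)))
  invisible(x)
}

#' @describeIn simulate_blood Trajectory tibble of a blood simulation.
#' @param x,... For the `tidy`/`glance` methods: a `blood_sim` object; unused.
#' @export
tidy.blood_sim <- function(x, ...) x$series

#' @describeIn simulate_blood One-row scenario summary with the fasting
#'   readout.
#' @export
glance.blood_sim <- function(x, ...) {
  tibble(
    days = x$days,
    f_pah = x$f_pah,
    daily_phe_g = x$schedule$daily_phe_g,
    fasting_phe_umol_l = fasting_phe(x)
  )
}

#' Fasting plasma Phe readout
#'
#' Plasma Phe sampled 14 hours after the final day's last meal (with the
#' default 0/4/10 h schedule: 8:00 AM the next morning), converted to
#' umol/L. This is the readout used for all steady-state scans.
#'
#' @param sim A `blood_sim` object from [simulate_blood()].
#' @return Fasting plasma Phe, umol/L.
#' @export
fasting_phe <- function(sim) {
  if (!inherits(sim, "blood_sim")) abort_input("`sim` must be a blood_sim.")
  i <- which.min(abs(sim$series$t_hr - sim$t_fasting_hr))
  if (abs(sim$series$t_hr[i] - sim$t_fasting_hr) > 1e-6) {
    abort_input("Fasting readout time is not on the output grid.")
  }
  sim$series$phe_mmol_l[i] * 1000
}

#' Fasting equilibrium of the meal-free blood model
#'
#' Solves the scalar steady-state condition of the fasting (no-meal) model,
#' `v_npd = pah_rate + trans_rate + renal_rate`, by bracketed root-finding.
#' The long-horizon limit of a 0 g/day simulation converges to this root.
#'
#' @param f_pah Fraction of healthy PAH activity.
#' @param params A [blood_params()] object.
#' @return Equilibrium plasma Phe, mmol/L.
#' @examples
#' fasting_equilibrium(f_pah = 0) # classical PKU fasting equilibrium
#' @export
fasting_equilibrium <- function(f_pah = 0, params = blood_params()) {
  check_nonneg(f_pah, "f_pah")
  g <- function(p) params$v_npd -
    (pah_rate(p, f_pah, params) + trans_rate(p, params) + renal_rate(p, params))
  uniroot(g, interval = c(1e-9, 100), tol = 1e-10)$root
}

#' Scan plasma Phe lowering across dietary Phe reductions
#'
#' Runs the blood model at the baseline diet and at each reduced diet, and
#' reports the percent lowering of the fasting readout:
#' `100 * (1 - fasting(reduced) / fasting(baseline))`.
#'
#' @param reductions Fractions of dietary Phe removed, in \[0, 1\].
#' @param f_pah Fraction of healthy PAH activity.
#' @param base_g_per_day Baseline dietary Phe, g/day.
#' @param days Simulation length per scenario, days.
#' @param params A [blood_params()] object.
#' @param times_hr Meal times, hours.
#' @return A tibble with columns `reduction`, `fasting_phe_umol_l`,
#'   `pct_lowering`.
#' @examples
#' diet_reduction_scan(c(0.2, 0.5), days = 60)
#' @export
diet_reduction_scan <- function(reductions, f_pah = 0, base_g_per_day = 2.5,
                                days = 180, params = blood_params(),
                                times_hr = c(0, 4, 10)) {
  check_nonneg(reductions, "reductions")
  if (any(reductions > 1)) abort_input("`reductions` must be in [0, 1].")
  run <- function(r) {
    fasting_phe(simulate_blood(
      days = days,
      schedule = meal_schedule(base_g_per_day, times_hr, removal_fraction = r),
      f_pah = f_pah, params = params
    ))
  }
  base <- run(0)
  fast <- vapply(reductions, run, numeric(1))
  tibble(
    reduction = reductions,
    fasting_phe_umol_l = fast,
    pct_lowering = 100 * (1 - fast / base)
  )
}

#' Daily Phe consumption required for a target plasma Phe lowering
#'
#' Inverts the diet-removal simulation: finds, by bracketed root-finding,
#' the daily luminal Phe consumption (mg/day, split equally across meals)
#' at which the fasting readout is lowered by `target_pct` percent relative
#' to the unmodified diet.
#'
#' @param target_pct Target lowering, percent (0 < target < maximum
#'   achievable at 100% removal).
#' @param f_pah Fraction of healthy PAH activity.
#' @param base_g_per_day Baseline dietary Phe, g/day.
#' @param days Simulation length per evaluation, days.
#' @param params A [blood_params()] object.
#' @param times_hr Meal times, hours.
#' @param tol_mg Root-finding tolerance on the consumption, mg/day.
#' @return Required consumption, mg/day.
#' @examples
#' \donttest{
#' required_consumption_for_lowering(30) # ~780 mg/day for classical PKU
#' }
#' @export
required_consumption_for_lowering <- function(target_pct, f_pah = 0,
                                              base_g_per_day = 2.5,
                                              days = 180,
                                              params = blood_params(),
                                              times_hr = c(0, 4, 10),
                                              tol_mg = 1) {
  check_nonneg(target_pct, "target_pct"); check_scalar(target_pct, "target_pct")
  if (target_pct == 0) return(0)
  daily_mg <- base_g_per_day * 1000
  n_meals <- length(times_hr)
  low_at <- function(mg_day) {
    sched <- meal_schedule(base_g_per_day, times_hr,
                           removal_mg_per_meal = mg_day / n_meals)
    fasting_phe(simulate_blood(days = days, schedule = sched,
                               f_pah = f_pah, params = params))
  }
  base <- low_at(0)
  max_low <- 100 * (1 - low_at(daily_mg) / base)
  if (target_pct >= max_low) {
    abort("Target lowering exceeds the maximum achievable by dietary removal.",
          class = c("phesim_domain_error", "phesim_error"))
  }
  uniroot(
    function(mg) 100 * (1 - low_at(mg) / base) - target_pct,
    interval = c(0, daily_mg), tol = tol_mg
  )$root
}

#' Attribute Phe elimination to its three pathways
#'
#' Integrates the PAH, transaminase and renal elimination fluxes over the
#' final simulated day (trapezoidal quadrature on the dense output grid) and
#' normalizes them to fractions of total elimination.
#'
#' @param sim A `blood_sim` object from [simulate_blood()].
#' @return A tibble with columns `pathway` (`"pah"`, `"trans"`, `"renal"`),
#'   `integral_mmol_l` (24-h integrated flux) and `fraction` (summing to 1).
#' @examples
#' elimination_attribution(simulate_blood(days = 30, f_pah = 0))
#' @export
elimination_attribution <- function(sim) {
  if (!inherits(sim, "blood_sim")) abort_input("`sim` must be a blood_sim.")
  s <- sim$series
  t1 <- max(s$t_hr)
  d <- s[s$t_hr >= t1 - 24, ]
  p <- sim$params
  ints <- c(
    pah = trapz(d$t_hr, pah_rate(d$phe_mmol_l, sim$f_pah, p)),
    trans = trapz(d$t_hr, trans_rate(d$phe_mmol_l, p)),
    renal = trapz(d$t_hr, renal_rate(d$phe_mmol_l, p))
  )
  tibble(
    pathway = names(ints),
    integral_mmol_l = unname(ints),
    fraction = unname(ints / sum(ints))
  )
}
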