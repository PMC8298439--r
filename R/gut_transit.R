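#' Power-exponential gastric emptying curve
#'
#' Fraction of initial stomach contents remaining at time `t`:
#' `f(t) = 2^(-(t / t_half)^beta)`. `f(0) = 1` and `f(t_half) = 0.5` by
#' construction; `beta` > 1 produces the sigmoidal lag typical of solid
#' meals, `beta` = 1 reduces to first-order emptying.
#'
#' @param t Time since dosing, minutes. Vectorized.
#' @param beta Emptying shape parameter (> 0).
#' @param t_half Half-emptying time, minutes.
#' @return Fraction remaining in \[0, 1\].
#' @examples
#' gastric_fraction_remaining(43, beta = 1.12, t_half = 43) # 0.5
#' @export
gastric_fraction_remaining <- function(t, beta = 1.12, t_half = 43) {
  check_nonneg(t, "t")
  check_pos(beta, "beta"); check_pos(t_half, "t_half")
  2^(-(t / t_half)^beta)
}

#' Instantaneous gastric emptying hazard
#'
#' The fractional emptying rate `k(t) = -f'(t) / f(t)` implied by the
#' power-exponential curve, i.e. the rate at which a well-mixed tracer must
#' leave the stomach so that contents initialized at `t = 0` decay exactly
#' along `f(t)`: `k(t) = ln(2) * beta / t_half * (t / t_half)^(beta - 1)`.
#' For `beta` = 1 this is the constant first-order rate `ln(2) / t_half`;
#' for `beta` > 1 it starts at 0 (emptying lag).
#'
#' @inheritParams gastric_fraction_remaining
#' @return Emptying rate, min^-1.
#' @examples
#' gastric_emptying_hazard(0, beta = 1.12)       # 0: lag phase
#' gastric_emptying_hazard(10, beta = 1)         # log(2)/43
#' @export
gastric_emptying_hazard <- function(t, beta = 1.12, t_half = 43) {
  check_nonneg(t, "t")
  check_pos(beta, "beta"); check_pos(t_half, "t_half")
  k <- log(2) * beta / t_half * (t / t_half)^(beta - 1)
  # t = 0: the hazard is 0 for beta > 1, ln2/t_half at beta = 1, +Inf below
  if (beta < 1) k[t == 0] <- Inf
  k
}

#' Postprandial gastric pH trajectory
#'
#' Exponential decay of gastric pH from the buffered post-meal value to the
#' acidic floor: `(ph0 - ph_min) * exp(-k_ph * t) + ph_min`.
#'
#' @param t Time since dosing, minutes. Vectorized.
#' @param params A [gut_params()] object supplying `ph0`, `ph_min`, `k_ph`.
#' @return Gastric pH.
#' @examples
#' gastric_ph(c(0, 60, 360), gut_params("human"))
#' @export
gastric_ph <- function(t, params = gut_params("human")) {
  check_nonneg(t, "t")
  (params$ph0 - params$ph_min) * exp(-params$k_ph * t) + params$ph_min
}

# Stomach liquid volume (mL): fasted secretion baseline plus the dose
# vehicle, which empties along with the contents.
stomach_volume <- function(t, params) {
  params$vol_st +
    params$dose_vehicle_ml * gastric_fraction_remaining(t, params$beta, params$t_half)
}

# PAL flux on compartment amounts. Because vmax is per cell (per 1e9 CFU),
# the compartment volume enters only through the Km and Ki concentration
# terms: total flux (umol/min) = vmax * cells/1e9 * MM(conc) * Ki_pH * Ki_TCA.
compartment_pal_flux <- function(phe_amt, tca_amt, cells, vol_ml, ph, kin) {
  phe_amt <- max(phe_amt, 0)
  conc <- phe_amt / vol_ml
  tca <- max(tca_amt, 0) / vol_ml
  kin$vmax * conc / (kin$km + conc) * (cells / 1e9) *
    ki_ph(ph, kin) * ki_tca(tca, kin)
}

# Right-hand side of the two-compartment upper-GI system, in amounts (umol,
# CFU) and minutes. State: cells_st, cells_si, phe_st, tca_st, phe_si,
# tca_si, phe_absorbed, tca_absorbed.
gi_rhs <- function(t, y, parms) {
  gp <- parms$gut; kin <- parms$kin
  k <- gastric_emptying_hazard(t, gp$beta, gp$t_half)
  vst <- stomach_volume(t, gp)
  flux_st <- compartment_pal_flux(y[["phe_st"]], y[["tca_st"]], y[["cells_st"]],
                                  vst, gastric_ph(t, gp), kin)
  flux_si <- compartment_pal_flux(y[["phe_si"]], y[["tca_si"]], y[["cells_si"]],
                                  gp$vol_si, gp$ph_si, kin)
  list(c(
    cells_st = -k * y[["cells_st"]],
    cells_si = k * y[["cells_st"]],
    phe_st = -flux_st - k * y[["phe_st"]],
    tca_st = flux_st - k * y[["tca_st"]],
    phe_si = -flux_si + k * y[["phe_st"]] - gp$lam * y[["phe_si"]],
    tca_si = flux_si + k * y[["tca_st"]] - gp$lam * y[["tca_si"]],
    phe_absorbed = gp$lam * y[["phe_si"]],
    tca_absorbed = gp$lam * y[["tca_si"]]
  ))
}

#' Simulate an oral synthetic-biotic dose through the upper GI tract
#'
#' Integrates the two-compartment stomach/small-intestine system over the
#' urine-collection horizon: the dose and meal Phe start in the stomach,
#' empty into the small intestine along the power-exponential curve, PAL
#' converts luminal Phe to TCA in both compartments (at the decaying gastric
#' pH and the fixed SI pH), and Phe/TCA are absorbed from the SI with
#' first-order kinetics. Cells are neither absorbed nor killed, so
#' `cells_st + cells_si` equals the dose throughout.
#'
#' The predicted urinary hippurate (HA) equals total TCA produced by the
#' horizon (luminal plus absorbed), under 1:1 TCA-to-HA stoichiometry with
#' complete urinary recovery.
#'
#' @param dose_cfu Oral dose, CFU.
#' @param meal_phe_g Meal Phe, grams; overrides the registry's initial
#'   stomach Phe as `meal_phe_g / 165.19 * 1e6` umol. `NULL` uses the
#'   registry value.
#' @param params A [gut_params()] object.
#' @param kin A [pal_params()] object.
#' @param horizon_min Simulation horizon, minutes (default 360, the 6-h
#'   urine-collection window).
#' @param dt_out Output grid spacing, minutes.
#' @return An object of class `gi_sim`: a list with `series` (tibble of the
#'   state trajectory plus `gastric_ph`), `phe_consumed_umol`,
#'   `predicted_ha_umol`, `predicted_ha_mg` (via HA molar mass 179.17 g/mol,
#'   a display conversion), `horizon_min`, `dose_cfu` and the parameter
#'   objects.
#' @examples
#' sim <- simulate_gi_dose(1e11, meal_phe_g = 2.0)
#' glance(sim)
#' @export
simulate_gi_dose <- function(dose_cfu, meal_phe_g = NULL,
                             params = gut_params("human"),
                             kin = pal_params(),
                             horizon_min = 360, dt_out = 1) {
  check_nonneg(dose_cfu, "dose_cfu"); check_scalar(dose_cfu, "dose_cfu")
  check_pos(horizon_min, "horizon_min")
  if (!inherits(params, "gut_params")) abort_input("`params` must be gut_params().")
  if (!inherits(kin, "pal_params")) abort_input("`kin` must be pal_params().")
  phe_st0 <- if (is.null(meal_phe_g)) params$phe_st0 else {
    check_nonneg(meal_phe_g, "meal_phe_g")
    meal_phe_g / MW_PHE * 1e6
  }
  y0 <- c(cells_st = dose_cfu, cells_si = 0,
          phe_st = phe_st0, tca_st = 0,
          phe_si = params$phe_si0, tca_si = 0,
          phe_absorbed = 0, tca_absorbed = 0)
  times <- sort(unique(c(seq(0, horizon_min, by = dt_out), horizon_min)))
  out <- integrate_checked(
    y = y0, times = times, func = gi_rhs,
    parms = list(gut = params, kin = kin),
    what = "simulate_gi_dose", rtol = 1e-8, atol = 1e-10
  )
  series <- as_tibble(as.data.frame(out))
  names(series)[1] <- "t_min"
  series$gastric_ph <- gastric_ph(series$t_min, params)
  fin <- series[nrow(series), ]
  consumed <- fin$tca_st + fin$tca_si + fin$tca_absorbed
  structure(
    list(
      series = series,
      phe_consumed_umol = consumed,
      predicted_ha_umol = consumed,
      predicted_ha_mg = consumed * MW_HA / 1000,
      horizon_min = horizon_min,
      dose_cfu = dose_cfu,
      meal_phe_g = meal_phe_g %||% (phe_st0 * MW_PHE / 1e6),
      params = params,
      kin = kin
    ),
    class = "gi_sim"
  )
}

# Molar masses (g/mol): phenylalanine and hippuric acid (display conversion).
MW_PHE <- 165.19
MW_HA <- 179.17

#' @export
print.gi_sim <- function(x, ...) {
  cat(sprintf("<gi_sim> %s, dose %.3g CFU, %.3g g Phe meal, %g min\n",
              x$params$species_label, x$dose_cfu, x$meal_phe_g, x$horizon_min))
  cat(sprintf("  Phe consumed by PAL: %.4g umol\n", x$phe_consumed_umol))
  cat(sprintf("  predicted urinary HA: %.4g umol (%.4g mg)\n",
              x$predicted_ha_umol, x$predicted_ha_mg))
  invisible(x)
}

#' @describeIn simulate_gi_dose Trajectory tibble of a GI simulation.
#' @param x,... For the `tidy`/`glance` methods: a `gi_sim` object; unused.
#' @export
tidy.gi_sim <- function(x, ...) x$series

#' @describeIn simulate_gi_dose One-row summary (dose, consumption, HA).
#' @export
glance.gi_sim <- function(x, ...) {
  tibble(
    species = x$params$species_label,
    dose_cfu = x$dose_cfu,
    meal_phe_g = x$meal_phe_g,
    horizon_min = x$horizon_min,
    phe_consumed_umol = x$phe_consumed_umol,
    predicted_ha_umol = x$predicted_ha_umol,
    predicted_ha_mg = x$predicted_ha_mg
  )
}

#' Urinary hippurate dose-response with kinetic-uncertainty bands
#'
#' Runs [simulate_gi_dose()] across a dose grid at the PAL point estimates
#' and, optionally, at the 95% CI corner parameter sets: (low Km, high Vmax)
#' bounds activity from above, (high Km, low Vmax) from below.
#'
#' @param doses Vector of doses, CFU.
#' @param meal_phe_g Meal Phe, grams (`NULL` = registry initial value).
#' @param params A [gut_params()] object.
#' @param kin A [pal_params()] object.
#' @param with_ci Compute `ha_lo`/`ha_hi` CI-corner bounds?
#' @param horizon_min Simulation horizon, minutes.
#' @return A tibble with columns `dose_cfu`, `ha_umol` and, when `with_ci`,
#'   `ha_lo`, `ha_hi`.
#' @examples
#' ha_dose_response(c(0, 1e11), meal_phe_g = 2)
#' @export
ha_dose_response <- function(doses, meal_phe_g = NULL,
                             params = gut_params("human"),
                             kin = pal_params(),
                             with_ci = TRUE, horizon_min = 360) {
  check_nonneg(doses, "doses")
  corners <- pal_ci_corners(kin)
  run <- function(d, k) simulate_gi_dose(d, meal_phe_g, params, k,
                                         horizon_min)$predicted_ha_umol
  out <- tibble(
    dose_cfu = doses,
    ha_umol = vapply(doses, run, numeric(1), k = corners$point)
  )
  if (with_ci) {
    out$ha_lo <- vapply(doses, run, numeric(1), k = corners$lo)
    out$ha_hi <- vapply(doses, run, numeric(1), k = corners$hi)
  }
  out
}
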