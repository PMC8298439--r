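#' Blood phenylalanine metabolism parameters
#'
#' Constants of the extended plasma Phe model: first-order gut absorption
#' (`ka_gut`, hr^-1), net protein breakdown input (`v_npd`, (mmol/L)/hr),
#' PAH elimination with substrate activation (`vmax_pah`, `km_pah`,
#' `ka_pah`), transaminase elimination (`vmax_trans`, `km_trans`), renal
#' clearance (`cl_renal`), and the gut-to-plasma unit conversion constants
#' (Phe molar mass `mw_phe`, distribution volume `vd` L/kg, body weight
#' `weight` kg). `phe0` is the default initial plasma Phe for PKU scenarios
#' (1.18 mmol/L).
#'
#' The fraction of healthy PAH activity (`f_pah`, 0 for classical PKU, 1 for
#' a healthy subject) is a scenario input, passed to the simulation
#' functions rather than stored here.
#'
#' @param ka_gut Gut absorption rate, hr^-1.
#' @param v_npd Net protein breakdown rate, (mmol/L)/hr.
#' @param vmax_pah Maximum PAH elimination rate in a healthy subject,
#'   (mmol/L)/hr.
#' @param km_pah PAH Michaelis constant, mmol/L.
#' @param ka_pah PAH substrate-activation constant, mmol/L.
#' @param vmax_trans Maximum transaminase rate, (mmol/L)/hr.
#' @param km_trans Transaminase Michaelis constant, mmol/L.
#' @param cl_renal Renal clearance per body weight, (L/kg)/hr.
#' @param mw_phe Phe molar mass, g/mol.
#' @param vd Phe distribution volume, L/kg.
#' @param weight Body weight, kg.
#' @param phe0 Default initial plasma Phe, mmol/L.
#' @return An object of class `blood_params` (a named list).
#' @examples
#' gut_to_plasma_factor(blood_params())
#' @export
blood_params <- function(ka_gut = 0.25,
                         v_npd = 0.012,
                         vmax_pah = 0.9,
                         km_pah = 0.51,
                         ka_pah = 0.54,
                         vmax_trans = 0.063,
                         km_trans = 1.37,
                         cl_renal = 5.696e-4,
                         mw_phe = 165.19,
                         vd = 0.5,
                         weight = 70,
                         phe0 = 1.18) {
  p <- list(ka_gut = ka_gut, v_npd = v_npd, vmax_pah = vmax_pah,
            km_pah = km_pah, ka_pah = ka_pah, vmax_trans = vmax_trans,
            km_trans = km_trans, cl_renal = cl_renal, mw_phe = mw_phe,
            vd = vd, weight = weight, phe0 = phe0)
  for (nm in names(p)) check_pos(p[[nm]], nm)
  structure(p, class = "blood_params")
}

#' @export
print.blood_params <- function(x, ...) {
  cat("<blood_params> plasma Phe metabolism\n")
  cat(sprintf("  absorption ka_gut %.3g /hr; protein breakdown %.3g (mmol/L)/hr\n",
              x$ka_gut, x$v_npd))
  cat(sprintf("  PAH: vmax %.3g, Km %.3g, Ka %.3g; transaminase: vmax %.3g, Km %.3g\n",
              x$vmax_pah, x$km_pah, x$ka_pah, x$vmax_trans, x$km_trans))
  cat(sprintf("  renal CL %.4g (L/kg)/hr; Vd %.3g L/kg; weight %.3g kg\n",
              x$cl_renal, x$vd, x$weight))
  invisible(x)
}

#' Daily meal schedule with optional luminal Phe removal
#'
#' Describes the dietary Phe input of the blood model: total daily Phe split
#' across meals at fixed clock times, with an optional specification of Phe
#' removed from each meal before absorption (the action of a luminal
#' Phe-consuming agent, or a prescribed dietary reduction).
#'
#' @param daily_phe_g Total dietary Phe, g/day (default 2.5, the Phe content
#'   of a 50 g protein diet).
#' @param times_hr Meal times in hours relative to the daily anchor
#'   (8:00 AM); default `c(0, 4, 10)`.
#' @param fractions Fraction of daily Phe in each meal; defaults to an even
#'   split. Must sum to 1.
#' @param removal_fraction Fraction of each meal's Phe removed before
#'   absorption, in \[0, 1\].
#' @param removal_mg_per_meal Alternative absolute removal per meal, mg;
#'   overrides `removal_fraction` when non-`NULL`. Clipped at each meal's
#'   content.
#' @return An object of class `meal_schedule`.
#' @examples
#' meal_schedule(2.5, removal_fraction = 0.3)
#' @export
meal_schedule <- function(daily_phe_g = 2.5,
                          times_hr = c(0, 4, 10),
                          fractions = NULL,
                          removal_fraction = 0,
                          removal_mg_per_meal = NULL) {
  check_nonneg(daily_phe_g, "daily_phe_g"); check_scalar(daily_phe_g, "daily_phe_g")
  check_nonneg(times_hr, "times_hr")
  if (any(times_hr >= 24)) abort_input("`times_hr` must lie within one day (< 24).")
  if (any(duplicated(times_hr))) abort_input("`times_hr` must be distinct.")
  n <- length(times_hr)
  fractions <- fractions %||% rep(1 / n, n)
  check_nonneg(fractions, "fractions")
  if (length(fractions) != n) {
    abort_input("`fractions` must match `times_hr` in length.")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort_input("`fractions` must sum to 1.")
  check_nonneg(removal_fraction, "removal_fraction")
  check_scalar(removal_fraction, "removal_fraction")
  if (removal_fraction > 1) abort_input("`removal_fraction` must be <= 1.")
  if (!is.null(removal_mg_per_meal)) {
    check_nonneg(removal_mg_per_meal, "removal_mg_per_meal")
    check_scalar(removal_mg_per_meal, "removal_mg_per_meal")
  }
  structure(
    list(daily_phe_g = daily_phe_g, times_hr = sort(times_hr),
         fractions = fractions[order(times_hr)],
         removal_fraction = removal_fraction,
         removal_mg_per_meal = removal_mg_per_meal),
    class = "meal_schedule"
  )
}

# Net meal boluses (mg) after luminal removal, one per meal. Absolute
# removal is clipped at each meal's content.
meal_boluses_mg <- function(schedule) {
  meal_mg <- schedule$daily_phe_g * 1000 * schedule$fractions
  if (!is.null(schedule$removal_mg_per_meal)) {
    pmax(meal_mg - pmin(schedule$removal_mg_per_meal, meal_mg), 0)
  } else {
    meal_mg * (1 - schedule$removal_fraction)
  }
}

#' @export
print.meal_schedule <- function(x, ...) {
  cat(sprintf("<meal_schedule> %.3g g Phe/day at hours {%s}\n",
              x$daily_phe_g, paste(x$times_hr, collapse = ", ")))
  if (!is.null(x$removal_mg_per_meal)) {
    cat(sprintf("  removal: %.4g mg per meal (clipped at meal content)\n",
                x$removal_mg_per_meal))
  } else if (x$removal_fraction > 0) {
    cat(sprintf("  removal: %.1f%% of each meal\n", 100 * x$removal_fraction))
  }
  invisible(x)
}
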