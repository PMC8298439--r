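#' Whole-cell PAL kinetic parameters
#'
#' Bundles the kinetic constants describing phenylalanine ammonia lyase (PAL)
#' activity of the engineered strain measured in a whole-cell context: the
#' Michaelis-Menten constants with their 95% confidence bounds, the linear
#' pH-activity coefficients and the exponential trans-cinnamic acid (TCA)
#' product-inhibition coefficients.
#'
#' The defaults are the strain's in vitro estimates: `km` 0.0184 umol/mL
#' (95% CI 0.005-0.0442), `vmax` 0.0162 umol/(min x 1e9 CFU)
#' (95% CI 0.0154-0.0171). PAL activity responds linearly to environmental pH
#' (`ki_ph_slope * pH + ki_ph_intercept`, clamped to \[0, 1\]) and decays
#' exponentially with extracellular TCA
#' (`ki_tca_amp * exp(-ki_tca_rate * TCA) + ki_tca_floor`).
#'
#' @param km Michaelis-Menten constant for Phe, umol/mL.
#' @param vmax Maximum TCA production rate, umol/(min x 1e9 CFU).
#' @param km_ci Length-2 numeric, 95% confidence bounds on `km`.
#' @param vmax_ci Length-2 numeric, 95% confidence bounds on `vmax`.
#' @param ki_ph_slope,ki_ph_intercept Coefficients of the linear pH-activity
#'   relationship (per pH unit; unitless).
#' @param ki_tca_amp,ki_tca_rate,ki_tca_floor Coefficients of the exponential
#'   TCA inhibition curve (unitless; per-mM; unitless). With the defaults the
#'   curve equals 1 at zero TCA and decays to the floor 0.33.
#' @return An object of class `pal_params` (a named list).
#' @examples
#' kin <- pal_params()
#' ki_tca(1, kin)
#' @export
pal_params <- function(km = 0.0184,
                       vmax = 0.0162,
                       km_ci = c(0.005, 0.0442),
                       vmax_ci = c(0.0154, 0.0171),
                       ki_ph_slope = 0.25,
                       ki_ph_intercept = -0.7,
                       ki_tca_amp = 0.67,
                       ki_tca_rate = 0.53,
                       ki_tca_floor = 0.33) {
  check_pos(km, "km"); check_scalar(km, "km")
  check_pos(vmax, "vmax"); check_scalar(vmax, "vmax")
  if (length(km_ci) != 2L || length(vmax_ci) != 2L) {
    abort_input("`km_ci` and `vmax_ci` must each have two elements (lo, hi).")
  }
  check_pos(km_ci, "km_ci"); check_pos(vmax_ci, "vmax_ci")
  if (km_ci[1] > km || km > km_ci[2]) {
    abort_input("`km` must lie inside `km_ci`.")
  }
  if (vmax_ci[1] > vmax || vmax > vmax_ci[2]) {
    abort_input("`vmax` must lie inside `vmax_ci`.")
  }
  check_finite(c(ki_ph_slope, ki_ph_intercept), "ki_ph coefficients")
  check_nonneg(c(ki_tca_amp, ki_tca_rate, ki_tca_floor), "ki_tca coefficients")
  structure(
    list(
      km = km, vmax = vmax,
      km_lo = km_ci[1], km_hi = km_ci[2],
      vmax_lo = vmax_ci[1], vmax_hi = vmax_ci[2],
      ki_ph_slope = ki_ph_slope, ki_ph_intercept = ki_ph_intercept,
      ki_tca_amp = ki_tca_amp, ki_tca_rate = ki_tca_rate,
      ki_tca_floor = ki_tca_floor
    ),
    class = "pal_params"
  )
}

#' @export
print.pal_params <- function(x, ...) {
  cat("<pal_params> whole-cell PAL kinetics\n")
  cat(sprintf("  Km   %.4g umol/mL   (95%% CI %.4g-%.4g)\n", x$km, x$km_lo, x$km_hi))
  cat(sprintf("  Vmax %.4g umol/(min x 1e9 CFU) (95%% CI %.4g-%.4g)\n",
              x$vmax, x$vmax_lo, x$vmax_hi))
  cat(sprintf("  pH inhibition:  clamp(%.3g pH %+.3g, 0, 1)\n",
              x$ki_ph_slope, x$ki_ph_intercept))
  cat(sprintf("  TCA inhibition: %.3g exp(-%.3g TCA) + %.3g\n",
              x$ki_tca_amp, x$ki_tca_rate, x$ki_tca_floor))
  invisible(x)
}

# Parameter sets at the 95% CI corners used for uncertainty bands.
# High activity pairs the low Km with the high Vmax; low activity the reverse.
pal_ci_corners <- function(kin) {
  list(
    point = kin,
    hi = pal_params(
      km = kin$km_lo, vmax = kin$vmax_hi,
      km_ci = c(kin$km_lo, kin$km_hi), vmax_ci = c(kin$vmax_lo, kin$vmax_hi),
      ki_ph_slope = kin$ki_ph_slope, ki_ph_intercept = kin$ki_ph_intercept,
      ki_tca_amp = kin$ki_tca_amp, ki_tca_rate = kin$ki_tca_rate,
      ki_tca_floor = kin$ki_tca_floor
    ),
    lo = pal_params(
      km = kin$km_hi, vmax = kin$vmax_lo,
      km_ci = c(kin$km_lo, kin$km_hi), vmax_ci = c(kin$vmax_lo, kin$vmax_hi),
      ki_ph_slope = kin$ki_ph_slope, ki_ph_intercept = kin$ki_ph_intercept,
      ki_tca_amp = kin$ki_tca_amp, ki_tca_rate = kin$ki_tca_rate,
      ki_tca_floor = kin$ki_tca_floor
    )
  )
}
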