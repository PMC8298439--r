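#' pH inhibition multiplier for PAL activity
#'
#' Whole-cell PAL activity falls off linearly with environmental pH. The raw
#' line `slope * pH + intercept` is clamped to \[0, 1\]: activity cannot be
#' negative, and relative activity is defined against the pH at which the
#' strain is fully active. With the default coefficients the multiplier
#' reaches 0 at pH 2.8 and saturates at 1 from pH 6.8 upward.
#'
#' @param ph Environmental pH (unitless). Vectorized.
#' @param params A [pal_params()] object supplying the line coefficients.
#' @return Inhibition multiplier in \[0, 1\], same length as `ph`.
#' @examples
#' ki_ph(c(2.8, 5, 6.8))
#' @export
ki_ph <- function(ph, params = pal_params()) {
  check_finite(ph, "ph")
  pmin(pmax(params$ki_ph_slope * ph + params$ki_ph_intercept, 0), 1)
}

#' TCA product-inhibition multiplier for PAL activity
#'
#' Extracellular trans-cinnamic acid (TCA), the PAL reaction product,
#' inhibits further PAL flux. Relative activity decays exponentially with
#' TCA concentration towards a floor:
#' `amp * exp(-rate * tca) + floor`, equal to 1 at zero TCA with the default
#' coefficients and approaching 0.33 at high TCA (up to ~60% inhibition).
#'
#' @param tca_mM TCA concentration in mM (= umol/mL). Vectorized.
#' @param params A [pal_params()] object supplying the decay coefficients.
#' @return Inhibition multiplier in (0, 1], same length as `tca_mM`.
#' @examples
#' ki_tca(c(0, 1, 8))
#' @export
ki_tca <- function(tca_mM, params = pal_params()) {
  check_nonneg(tca_mM, "tca_mM")
  params$ki_tca_amp * exp(-params$ki_tca_rate * tca_mM) + params$ki_tca_floor
}

#' Whole-cell PAL reaction flux
#'
#' Michaelis-Menten rate of Phe consumption (equivalently TCA production,
#' 1:1 stoichiometry) by a suspension of PAL-expressing cells, modulated by
#' the pH and TCA inhibition multipliers. Each cell is treated as one enzyme
#' equivalent; `vmax` is expressed per 1e9 CFU, so the cell density is scaled
#' by 1e9 explicitly here.
#'
#' @param phe_conc Phe concentration, umol/mL.
#' @param cells_per_ml Cell density, CFU/mL.
#' @param ph Environmental pH.
#' @param tca_conc TCA concentration, umol/mL (= mM).
#' @param params A [pal_params()] object.
#' @return Volumetric rate of Phe consumption, umol/(mL min). Zero when
#'   `phe_conc` is zero (the limit of the rate law, not a division error).
#' @examples
#' kin <- pal_params()
#' pal_flux(kin$km, 1e9, ph = 7, tca_conc = 0) # half-saturation: vmax / 2
#' @export
pal_flux <- function(phe_conc, cells_per_ml, ph, tca_conc = 0,
                     params = pal_params()) {
  check_nonneg(phe_conc, "phe_conc")
  check_nonneg(cells_per_ml, "cells_per_ml")
  check_nonneg(tca_conc, "tca_conc")
  check_finite(ph, "ph")
  # vmax * Phe / (Km + Phe) is the 0-safe algebraic form of vmax / (1 + Km/Phe)
  params$vmax * phe_conc / (params$km + phe_conc) *
    (cells_per_ml / 1e9) * ki_ph(ph, params) * ki_tca(tca_conc, params)
}

#' Simulate a closed in vitro PAL batch reaction
#'
#' Integrates the coupled Phe consumption / TCA production system for a fixed
#' cell density at fixed pH, as in an in vitro gastric simulation (IVS): the
#' fluid is buffered, so pH does not drift, while product inhibition builds up
#' as TCA accumulates. The system is closed, so `phe + tca` is conserved.
#'
#' @param phe0 Initial Phe concentration, umol/mL.
#' @param cells_per_ml Cell density, CFU/mL (constant over the run).
#' @param ph Buffered pH of the medium.
#' @param duration_min Simulation horizon, minutes.
#' @param params A [pal_params()] object.
#' @param record_times Times (min) at which to record the state. Defaults to
#'   a 1-minute grid over `[0, duration_min]`.
#' @param tca0 Initial TCA concentration, umol/mL (default 0).
#' @return A tibble of class `ivs_sim` with columns `t_min`, `phe`, `tca`
#'   (umol/mL), `cells_per_ml` and `ph`; the `pal_params` used are attached
#'   as the `"params"` attribute.
#' @examples
#' sim <- simulate_invitro_batch(20, 2.5e9, ph = 7, duration_min = 120)
#' tail(sim, 1)
#' @export
simulate_invitro_batch <- function(phe0, cells_per_ml, ph, duration_min = 120,
                                   params = pal_params(), record_times = NULL,
                                   tca0 = 0) {
  check_nonneg(phe0, "phe0"); check_scalar(phe0, "phe0")
  check_nonneg(cells_per_ml, "cells_per_ml"); check_scalar(cells_per_ml, "cells_per_ml")
  check_finite(ph, "ph"); check_scalar(ph, "ph")
  check_pos(duration_min, "duration_min"); check_scalar(duration_min, "duration_min")
  check_nonneg(tca0, "tca0")
  if (is.null(record_times)) {
    record_times <- seq(0, duration_min, by = min(1, duration_min))
  }
  check_nonneg(record_times, "record_times")
  times <- sort(unique(c(0, record_times)))

  rhs <- function(t, y, p) {
    v <- pal_flux(max(y[[1]], 0), cells_per_ml, ph, max(y[[2]], 0), p)
    list(c(-v, v))
  }
  out <- integrate_checked(
    y = c(phe = phe0, tca = tca0), times = times, func = rhs, parms = params,
    what = "simulate_invitro_batch", rtol = 1e-10, atol = 1e-12
  )
  res <- tibble(
    t_min = out[, "time"],
    phe = pmax(out[, "phe"], 0),
    tca = pmax(out[, "tca"], 0),
    cells_per_ml = cells_per_ml,
    ph = ph
  )
  res <- res[res$t_min %in% record_times, ]
  attr(res, "params") <- params
  class(res) <- c("ivs_sim", class(res))
  res
}
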