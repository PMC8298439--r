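#' Upper-gastrointestinal physiology parameters
#'
#' Species-specific parameters of the two-compartment stomach/small-intestine
#' transit model: the power-exponential gastric emptying curve (shape `beta`,
#' half-emptying time `t_half`), the postprandial gastric pH decay
#' (`ph0`, `ph_min`, `k_ph`), fixed small-intestinal pH, compartment liquid
#' volumes, the first-order intestinal absorption rate `lam`, and the initial
#' luminal Phe amounts.
#'
#' Two registries are built in. `"human"`: liquid-meal emptying
#' (`beta` 1.12, `t_half` 43 min), gastric pH decaying 6.0 to 1.71 at
#' 0.02653 min^-1, SI pH 6.5, fasted stomach 35 mL plus a 100 mL dose
#' vehicle, SI volume 54 mL, absorption 0.1019 min^-1, initial stomach Phe
#' 12108 umol (a 2.0 g Phe meal) and SI Phe 30.2 umol. `"nhp"` (cynomolgus
#' monkey): `t_half` 24.5 min, pH floor 1.97 with slow decay 0.004 min^-1,
#' SI pH 5.8, stomach 17 mL (no added vehicle), SI 13.7 mL, initial stomach
#' Phe 1513.41 umol and SI Phe 7.7 umol; emptying shape and absorption rate
#' carried over from the human parameterization.
#'
#' @param species `"human"` or `"nhp"`; selects the registry defaults.
#' @param ... Named overrides of individual fields (e.g. `t_half = 110`,
#'   `beta = 1.81` for a solid meal).
#' @return An object of class `gut_params` (a named list).
#' @examples
#' gut_params("nhp")$t_half
#' gut_params("human", beta = 1.81, t_half = 110) # solid meal emptying
#' @export
gut_params <- function(species = c("human", "nhp"), ...) {
  species <- tryCatch(match.arg(species),
                      error = function(e) abort_input("Unknown species registry."))
  base <- switch(species,
    human = list(
      beta = 1.12, t_half = 43, ph0 = 6.0, ph_min = 1.71, k_ph = 0.02653,
      ph_si = 6.5, vol_st = 35, vol_si = 54, lam = 0.1019,
      dose_vehicle_ml = 100, phe_st0 = 12108, phe_si0 = 30.2,
      species_label = "human"
    ),
    nhp = list(
      beta = 1.12, t_half = 24.5, ph0 = 6.0, ph_min = 1.97, k_ph = 0.004,
      ph_si = 5.8, vol_st = 17, vol_si = 13.7, lam = 0.1019,
      dose_vehicle_ml = 0, phe_st0 = 1513.41, phe_si0 = 7.7,
      species_label = "nhp"
    )
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    abort_input(sprintf("Unknown gut_params field(s): %s.",
                        paste(unknown, collapse = ", ")))
  }
  p <- modifyList(base, over)
  check_pos(p$beta, "beta"); check_pos(p$t_half, "t_half")
  check_pos(p$k_ph, "k_ph")
  check_pos(p$vol_st, "vol_st"); check_pos(p$vol_si, "vol_si")
  check_nonneg(p$lam, "lam"); check_nonneg(p$dose_vehicle_ml, "dose_vehicle_ml")
  check_nonneg(p$phe_st0, "phe_st0"); check_nonneg(p$phe_si0, "phe_si0")
  if (p$ph_min >= p$ph0) abort_input("`ph_min` must be below `ph0`.")
  structure(p, class = "gut_params")
}

#' @export
print.gut_params <- function(x, ...) {
  cat(sprintf("<gut_params> %s upper-GI physiology\n", x$species_label))
  cat(sprintf("  emptying: f(t) = 2^(-(t/%.4g)^%.4g)  [min]\n", x$t_half, x$beta))
  cat(sprintf("  gastric pH: %.3g -> %.3g at %.4g min^-1; SI pH %.3g\n",
              x$ph0, x$ph_min, x$k_ph, x$ph_si))
  cat(sprintf("  volumes: stomach %.4g mL (+%.4g mL vehicle), SI %.4g mL\n",
              x$vol_st, x$dose_vehicle_ml, x$vol_si))
  cat(sprintf("  absorption: %.4g min^-1; initial Phe: %.6g (St) / %.4g (SI) umol\n",
              x$lam, x$phe_st0, x$phe_si0))
  invisible(x)
}
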