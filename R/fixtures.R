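# Synthetic in vitro dataset generator.
#
# Emulates the strain-characterization experiments with known ground truth so
# the fitting machinery can be exercised (and its recovery rates calibrated)
# without any external data: rate vs Phe concentration, relative activity vs
# pH, relative activity vs exogenous TCA, and an IVS batch time course.

fixture_designs <- list(
  # doubling series over the experimental 0.312-40 mM range
  mm_rates = c(0.3125, 0.625, 1.25, 2.5, 5, 10, 20, 40),
  ph_activity = seq(4, 7, by = 0.5),
  tca_inhibition = c(0, 0.5, 1, 2, 4, 8),
  ivs_timecourse = seq(0, 120, by = 10)
)

#' Generate synthetic in vitro PAL datasets with known ground truth
#'
#' Evaluates the forward model for one of four assay designs and applies
#' multiplicative lognormal noise (Gaussian on the log scale, so measured
#' values stay positive and the assay CV scales with signal). Deterministic
#' under a fixed `seed`.
#'
#' Flavors:
#' \describe{
#'   \item{`mm_rates`}{TCA production rate vs initial Phe concentration
#'     (umol/mL). By default the instantaneous rate law is evaluated, so
#'     noiseless data sit exactly on the Michaelis-Menten curve and fits
#'     recover the generating parameters to numerical precision. Set
#'     `endpoint_min` (e.g. 60) to instead report the endpoint-average rate
#'     `TCA(endpoint)/endpoint` per 1e9 CFU from a batch simulation at
#'     `cells_per_ml`, mimicking assays that sample supernatant once: this
#'     includes substrate-depletion and product-inhibition bias.}
#'   \item{`ph_activity`}{Relative activity vs pH, from the unclamped linear
#'     relationship (the assay range keeps the line inside \[0, 1\]).}
#'   \item{`tca_inhibition`}{Relative activity vs exogenous TCA (mM), from
#'     the exponential decay law.}
#'   \item{`ivs_timecourse`}{TCA concentration vs time (min) from a batch
#'     simulation at `phe0` 20 umol/mL and `cells_per_ml`, buffered at `ph`.}
#' }
#'
#' @param flavor One of `"mm_rates"`, `"ph_activity"`, `"tca_inhibition"`,
#'   `"ivs_timecourse"`.
#' @param true_params A [pal_params()] object: the generating ground truth.
#' @param design_points Predictor levels (concentrations, pH values, TCA
#'   levels, or a time grid). Defaults mirror the characterization assays.
#' @param replicates Replicate measurements per level.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Optional integer; fixes the RNG locally (the caller's RNG
#'   state is untouched).
#' @param cells_per_ml Cell density for batch-based flavors, CFU/mL.
#' @param ph Buffer pH for batch-based flavors.
#' @param endpoint_min For `mm_rates` only: if non-`NULL`, report
#'   endpoint-average rates from a batch run of this duration (min) instead
#'   of instantaneous rates.
#' @return A tibble with columns `x`, `y`, `replicate`; the generating
#'   parameters and the noise-free curve are attached as attributes
#'   `"truth"` and `"y_true"`.
#' @examples
#' d <- simulate_rate_data("mm_rates", noise_cv = 0.15, seed = 1)
#' fit_michaelis_menten(d)
#' @export
simulate_rate_data <- function(flavor = c("mm_rates", "ph_activity",
                                          "tca_inhibition", "ivs_timecourse"),
                               true_params = pal_params(),
                               design_points = NULL,
                               replicates = 3L,
                               noise_cv = 0,
                               seed = NULL,
                               cells_per_ml = 2.5e9,
                               ph = 7,
                               endpoint_min = NULL) {
  flavor <- tryCatch(match.arg(flavor),
                     error = function(e) abort_input("Unknown fixture flavor."))
  if (!inherits(true_params, "pal_params")) {
    abort_input("`true_params` must be a pal_params() object.")
  }
  check_nonneg(noise_cv, "noise_cv"); check_scalar(noise_cv, "noise_cv")
  if (replicates < 1) abort_input("`replicates` must be >= 1.")
  x <- design_points %||% fixture_designs[[flavor]]
  check_nonneg(x, "design_points")

  y_true <- switch(flavor,
    mm_rates = {
      if (is.null(endpoint_min)) {
        true_params$vmax * x / (true_params$km + x)
      } else {
        check_pos(endpoint_min, "endpoint_min")
        vapply(x, function(s) {
          sim <- simulate_invitro_batch(s, cells_per_ml, ph,
                                        duration_min = endpoint_min,
                                        params = true_params,
                                        record_times = endpoint_min)
          tail(sim$tca, 1) / endpoint_min / (cells_per_ml / 1e9)
        }, numeric(1))
      }
    },
    ph_activity = true_params$ki_ph_slope * x + true_params$ki_ph_intercept,
    tca_inhibition = ki_tca(x, true_params),
    ivs_timecourse = {
      sim <- simulate_invitro_batch(20, cells_per_ml, ph,
                                    duration_min = max(x, 1),
                                    params = true_params, record_times = x)
      sim$tca[match(x, sim$t_min)]
    }
  )

  gen <- function() {
    n <- length(x) * replicates
    xs <- rep(x, times = replicates)
    yt <- rep(y_true, times = replicates)
    reps <- rep(seq_len(replicates), each = length(x))
    y <- if (noise_cv > 0) {
      sdlog <- sqrt(log1p(noise_cv^2))
      yt * exp(rnorm(n, mean = 0, sd = sdlog))
    } else yt
    tibble(x = xs, y = y, replicate = reps)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- dplyr::arrange(out, .data$x, .data$replicate)
  attr(out, "truth") <- true_params
  attr(out, "y_true") <- y_true
  out
}
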