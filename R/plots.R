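# ggplot2 visualizations for the main result types.

#' @export
autoplot.pal_fit <- function(object, n_grid = 200, ...) {
  xr <- range(object$data$x)
  grid <- tibble(x = seq(xr[1], xr[2], length.out = n_grid))
  grid$y <- predict_pal_fit(object, grid$x)
  xlab <- switch(object$model,
    michaelis_menten = "Phe (umol/mL)",
    ph_linear = "pH",
    tca_exponential = "TCA (mM)"
  )
  ylab <- switch(object$model,
    michaelis_menten = "rate (umol/(min x 1e9 CFU))",
    "relative activity"
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#d6467e", linewidth = 0.8) +
    ggplot2::labs(
      x = xlab, y = ylab,
      title = sprintf("%s fit", gsub("_", " ", object$model)),
      subtitle = if (is.na(object$r_squared)) NULL else
        sprintf("R² = %.4f", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ivs_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("t_min", "phe", "tca")],
                              -"t_min", names_to = "species",
                              values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (min)", y = "concentration (umol/mL)",
                  colour = NULL, title = "In vitro batch PAL reaction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gi_sim <- function(object, ...) {
  s <- object$series
  long <- tidyr::pivot_longer(
    s[, c("t_min", "phe_st", "tca_st", "phe_si", "tca_si",
          "phe_absorbed", "tca_absorbed")],
    -"t_min", names_to = "state", values_to = "umol"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$umol,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (min)", y = "amount (umol)", colour = NULL,
                  title = sprintf("Upper-GI transit, %.2g CFU", object$dose_cfu)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.blood_sim <- function(object, last_days = NULL, ...) {
  s <- object$series
  if (!is.null(last_days)) s <- s[s$t_hr >= max(s$t_hr) - last_days * 24, ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t_hr / 24,
                                  y = .data$phe_mmol_l * 1000)) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.6) +
    ggplot2::labs(x = "time (days)", y = "plasma Phe (umol/L)",
                  title = sprintf("Plasma Phe, f_PAH = %.2g, %.2g g Phe/day",
                                  object$f_pah, object$schedule$daily_phe_g)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table
#'
#' Plots percent plasma Phe lowering against dose (log axis) with the
#' kinetic-uncertainty ribbon when CI columns are present.
#'
#' @param curve A tibble from [dose_response_curve()].
#' @return A ggplot object.
#' @export
plot_dose_response <- function(curve) {
  if (!all(c("dose_cfu", "pct_lowering") %in% names(curve))) {
    abort_input("`curve` must come from dose_response_curve().")
  }
  d <- curve[curve$dose_cfu > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_cfu,
                                       y = .data$pct_lowering))
  if (all(c("lowering_lo", "lowering_hi") %in% names(d))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lowering_lo, ymax = .data$lowering_hi),
      fill = "#d6467e", alpha = 0.2
    )
  }
  p +
    ggplot2::geom_line(colour = "#d6467e", linewidth = 0.8) +
    ggplot2::geom_point(colour = "#d6467e") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (CFU, per administration)",
                  y = "plasma Phe lowering (%)",
                  title = "Predicted dose-response") +
    ggplot2::theme_minimal()
}
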