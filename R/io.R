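# Parameter registries, config round-tripping and tabular/JSON writers.
#
# All physical quantities carry explicit unit suffixes in config keys
# (t_half_min, daily_phe_g, ...) to prevent unit drift between the GI
# module (minutes, umol) and the blood module (hours, mmol/L, mg).

registry_builders <- list(
  pal_default = function(over) do.call(pal_params, over),
  human_gut = function(over) do.call(gut_params, c(list(species = "human"), over)),
  nhp_gut = function(over) do.call(gut_params, c(list(species = "nhp"), over)),
  blood_default = function(over) do.call(blood_params, over)
)

#' Built-in parameter registries
#'
#' Returns one of the four built-in parameter sets as its typed object:
#' `"pal_default"` (whole-cell PAL kinetics), `"human_gut"` / `"nhp_gut"`
#' (upper-GI physiology) or `"blood_default"` (plasma Phe metabolism).
#' Individual fields can be overridden; overrides are validated by the
#' corresponding constructor.
#'
#' @param name Registry name.
#' @param overrides Named list of field overrides (constructor arguments).
#' @return A `pal_params`, `gut_params` or `blood_params` object.
#' @examples
#' param_registry("nhp_gut")$t_half
#' @export
param_registry <- function(name = c("pal_default", "human_gut", "nhp_gut",
                                    "blood_default"),
                           overrides = list()) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort_input("Unknown registry name."))
  if (length(overrides) && is.null(names(overrides))) {
    abort_input("`overrides` must be a named list.")
  }
  registry_builders[[name]](overrides)
}

#' Read and write in vitro rate datasets as CSV
#'
#' The on-disk format is a plain CSV with header columns `x`, `y` and
#' (optionally) `replicate`.
#'
#' @param data A data frame with columns `x`, `y` and optional `replicate`.
#' @param path File path.
#' @return `read_rate_data()` returns a tibble; `write_rate_data()` returns
#'   `path` invisibly.
#' @export
write_rate_data <- function(data, path) {
  validate_rate_data(data, 1L)
  keep <- intersect(c("x", "y", "replicate"), names(data))
  readr::write_csv(data[keep], path)
  invisible(path)
}

#' @rdname write_rate_data
#' @export
read_rate_data <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("No such file: %s", path))
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) abort_input(sprintf("Failed to read %s: %s",
                                            path, conditionMessage(e)))
  )
  if (!all(c("x", "y") %in% names(out))) {
    abort_input(sprintf(
      "%s must contain columns `x` and `y` (found: %s).",
      path, paste(names(out), collapse = ", ")
    ))
  }
  if (!is.numeric(out$x) || !is.numeric(out$y)) {
    abort_input(sprintf("Columns `x` and `y` in %s must be numeric.", path))
  }
  out
}

#' Serialize a fit result to JSON
#'
#' Writes parameter names, point estimates, 95% confidence bounds and the
#' goodness of fit of a `pal_fit` to a JSON file.
#'
#' @param fit A `pal_fit` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "pal_fit")) abort_input("`fit` must be a pal_fit.")
  payload <- list(
    model = fit$model,
    parameters = lapply(seq_along(fit$estimates), function(i) {
      list(
        name = names(fit$estimates)[i],
        estimate = unname(fit$estimates[i]),
        std_error = unname(fit$std_errors[i]),
        conf_low = unname(fit$conf_low[i]),
        conf_high = unname(fit$conf_high[i])
      )
    }),
    r_squared = fit$r_squared,
    sigma = fit$sigma,
    nobs = fit$nobs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Round-trip parameter objects through YAML config files
#'
#' `write_params_yaml()` serializes a `pal_params`, `gut_params` or
#' `blood_params` object to a YAML file tagged with its registry type;
#' `read_params_yaml()` reconstructs the typed object through its
#' constructor, so every value is re-validated and overrides round-trip
#' losslessly.
#'
#' @param params A `pal_params`, `gut_params` or `blood_params` object.
#' @param path File path.
#' @return `write_params_yaml()` returns `path` invisibly;
#'   `read_params_yaml()` returns the reconstructed parameter object.
#' @export
write_params_yaml <- function(params, path) {
  type <- class(params)[1]
  if (!type %in% c("pal_params", "gut_params", "blood_params")) {
    abort_input("`params` must be a pal_params, gut_params or blood_params.")
  }
  yaml::write_yaml(c(list(type = type), unclass(params)), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("No such file: %s", path))
  raw <- yaml::read_yaml(path)
  type <- raw$type %||% abort_input("Config is missing the `type` field.")
  raw$type <- NULL
  switch(type,
    pal_params = pal_params(
      km = raw$km, vmax = raw$vmax,
      km_ci = c(raw$km_lo, raw$km_hi), vmax_ci = c(raw$vmax_lo, raw$vmax_hi),
      ki_ph_slope = raw$ki_ph_slope, ki_ph_intercept = raw$ki_ph_intercept,
      ki_tca_amp = raw$ki_tca_amp, ki_tca_rate = raw$ki_tca_rate,
      ki_tca_floor = raw$ki_tca_floor
    ),
    gut_params = do.call(gut_params, c(list(species = raw$species_label),
                                       raw[setdiff(names(raw), "species_label")])),
    blood_params = do.call(blood_params, raw),
    abort_input(sprintf("Unknown parameter type '%s' in %s.", type, path))
  )
}
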