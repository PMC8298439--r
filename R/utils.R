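# Input validation helpers. All user-facing errors carry the
# "phesim_invalid_input" (or more specific) condition class so callers can
# handle them programmatically.

abort_input <- function(msg, ...) {
  abort(msg, class = c("phesim_invalid_input", "phesim_error"), ...)
}

abort_fit <- function(msg, ...) {
  abort(msg, class = c("phesim_fit_error", "phesim_error"), ...)
}

abort_integration <- function(msg, ...) {
  abort(msg, class = c("phesim_integration_error", "phesim_error"), ...)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_input(sprintf("`%s` must be finite and numeric.", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite(x, name)
  if (any(x < 0)) {
    abort_input(sprintf("`%s` must be nonnegative.", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  check_finite(x, name)
  if (any(x <= 0)) {
    abort_input(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  if (length(x) != 1L) {
    abort_input(sprintf("`%s` must be a single value.", name))
  }
  invisible(x)
}

# Run a deSolve integration and fail loudly (with diagnostics) if the solver
# did not complete normally.
integrate_checked <- function(y, times, func, parms, what, ...) {
  out <- tryCatch(
    deSolve::ode(y = y, times = times, func = func, parms = parms, ...),
    error = function(e) {
      abort_integration(
        sprintf("ODE integration failed in %s: %s", what, conditionMessage(e))
      )
    }
  )
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0) {
    abort_integration(
      sprintf("ODE solver reported failure (istate = %d) in %s.", istate[1L], what)
    )
  }
  out
}

# Trapezoidal quadrature on an (x, y) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
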