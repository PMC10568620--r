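# Core dynamics: four-type exponential growth with irreversible mutation.
#
#   dw/dt = a w
#   dx/dt = g w + b x
#   dy/dt = h w + c y
#   dz/dt = k w + p x + q y + f z
#
# The system is lower-triangular, so it solves in closed form by
# variation of constants, cascading W -> {X, Y} -> Z. Writing each
# upstream population as a sum of exponentials, the Z equation picks up
# one resonance-free term per distinct eigenvalue:
#
#   w(t) = W0 e^{at}
#   x(t) = X0 e^{bt} + gW0 (e^{at} - e^{bt}) / (a - b)
#   y(t) = Y0 e^{ct} + hW0 (e^{at} - e^{ct}) / (a - c)
#   z(t) = Z0 e^{ft} + U_a (e^{at} - e^{ft}) / (a - f)
#               + U_b (e^{bt} - e^{ft}) / (b - f)
#               + U_c (e^{ct} - e^{ft}) / (c - f)
#   with U_a = kW0 + p gW0/(a-b) + q hW0/(a-c)   (direct W->Z plus the
#        U_b = p (X0 - gW0/(a-b))                 W->X->Z and W->Y->Z
#        U_c = q (Y0 - hW0/(a-c))                 double-mutation chains)
#
# The divided differences require distinct rates among {a,b,c,f} along
# each inflow path; near-coincident rates are delegated to the adaptive
# ODE integrator instead of L'Hopital limit formulas (they never occur at
# the default parameter values).

# relative closeness threshold below which the cascade formulas are
# considered degenerate
DEGENERACY_RTOL <- 1e-8

# internal: are any of the divided-difference denominators near zero?
is_degenerate_rates <- function(par, rtol = DEGENERACY_RTOL) {
  rates <- c(par$a, par$b, par$c, par$f)
  scale <- max(abs(rates), 1e-300)
  diffs <- c(
    par$a - par$b, par$a - par$c, par$a - par$f,
    par$b - par$f, par$c - par$f
  )
  any(abs(diffs) < rtol * scale)
}

# internal: closed-form advance of a state vector c(w,x,y,z) by dt days
cf_advance <- function(s, par, dt) {
  a <- par$a; b <- par$b; cc <- par$c; f <- par$f
  ea <- exp(a * dt); eb <- exp(b * dt); ec <- exp(cc * dt); ef <- exp(f * dt)
  W0 <- s[[1]]; X0 <- s[[2]]; Y0 <- s[[3]]; Z0 <- s[[4]]
  cxa <- par$g * W0 / (a - b)
  cya <- par$h * W0 / (a - cc)
  ua <- par$k * W0 + par$p * cxa + par$q * cya
  ub <- par$p * (X0 - cxa)
  uc <- par$q * (Y0 - cya)
  c(
    w = W0 * ea,
    x = cxa * ea + (X0 - cxa) * eb,
    y = cya * ea + (Y0 - cya) * ec,
    z = Z0 * ef + ua * (ea - ef) / (a - f) +
      ub * (eb - ef) / (b - f) + uc * (ec - ef) / (cc - f)
  )
}

# internal: adaptive-step integration of the same system
ode_advance <- function(s, par, dt, rel_tol = 1e-10, abs_tol = 1e-8) {
  if (dt == 0) {
    return(setNames(as.numeric(s), c("w", "x", "y", "z")))
  }
  rhs <- function(t, y, parms) {
    list(c(
      parms$a * y[1],
      parms$g * y[1] + parms$b * y[2],
      parms$h * y[1] + parms$c * y[3],
      parms$k * y[1] + parms$p * y[2] + parms$q * y[3] + parms$f * y[4]
    ))
  }
  sol <- deSolve::lsoda(
    y = as.numeric(s), times = c(0, dt), func = rhs, parms = par,
    rtol = rel_tol, atol = abs_tol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed to converge.", class = "tki_error_integration")
  }
  # clamp integrator noise of order abs_tol below zero
  setNames(pmax(as.numeric(sol[2, 2:5]), 0), c("w", "x", "y", "z"))
}

# internal: preferred advance — closed form, with an ODE fallback (flagged
# by a "tki_degenerate_fallback" message) when rates nearly coincide
advance_vector <- function(s, par, dt) {
  if (dt == 0) {
    return(setNames(as.numeric(s), c("w", "x", "y", "z")))
  }
  if (is_degenerate_rates(par)) {
    inform(
      paste0(
        "Near-coincident growth rates under regimen ",
        par$label %||% "?", "; using adaptive ODE integration."
      ),
      class = "tki_degenerate_fallback"
    )
    return(ode_advance(s, par, dt, rel_tol = 1e-12, abs_tol = 1e-10))
  }
  cf_advance(s, par, dt)
}

#' Advance a tumor state by the exact (closed-form) solution
#'
#' Propagates a state through `dt` days of a single constant drug regimen
#' using the analytic solution of the growth-mutation system (see
#' Details). When any two of the growth rates `a`, `b`, `c`, `f` that
#' enter a divided-difference denominator coincide to within a relative
#' 1e-8, the closed form is numerically unstable and the function falls
#' back to high-accuracy adaptive integration, signalling a
#' `tki_degenerate_fallback` message.
#'
#' @details The model is the linear cascade `dw/dt = a w`,
#'   `dx/dt = g w + b x`, `dy/dt = h w + c y`,
#'   `dz/dt = k w + p x + q y + f z`: exponential growth or decline per
#'   genotype plus irreversible mutation toward increasing resistance
#'   (no back-mutation, no carrying capacity). Counts are continuous
#'   non-negative reals.
#'
#' @param params Regimen parameter table (see [default_parameter_table()]).
#' @param state One-row state tibble (see [tumor_state()]).
#' @param regimen Regimen label to apply.
#' @param dt Duration in days (>= 0).
#' @return A one-row state tibble at `time + dt`.
#' @examples
#' default_parameter_table() |>
#'   closed_form_state(standard_initial_state(), "C", dt = 1000) |>
#'   state_total()
#' @export
closed_form_state <- function(params, state, regimen, dt) {
  par <- regimen_rates(params, regimen)
  if (dt < 0) abort("`dt` must be >= 0.", class = "tki_error_state")
  s <- advance_vector(as_state_vector(state), par, dt)
  tumor_state(s[["w"]], s[["x"]], s[["y"]], s[["z"]], time = state$time + dt)
}

#' Advance a tumor state by adaptive numerical integration
#'
#' Independent numerical reference for [closed_form_state()]: integrates
#' the same system with `deSolve::lsoda` at a user-set relative tolerance.
#'
#' @inheritParams closed_form_state
#' @param rel_tol Relative tolerance of the integrator (default 1e-10).
#' @param abs_tol Absolute tolerance in cells (default 1e-8).
#' @return A one-row state tibble at `time + dt`.
#' @export
numeric_reference_state <- function(params, state, regimen, dt,
                                    rel_tol = 1e-10, abs_tol = 1e-8) {
  par <- regimen_rates(params, regimen)
  if (dt < 0) abort("`dt` must be >= 0.", class = "tki_error_state")
  s <- ode_advance(as_state_vector(state), par, dt,
    rel_tol = rel_tol, abs_tol = abs_tol
  )
  tumor_state(s[["w"]], s[["x"]], s[["y"]], s[["z"]], time = state$time + dt)
}
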