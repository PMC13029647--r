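#' Parameters of the two-reactor cascade chemostat
#'
#' Bundles the parameters of the cascade growth model: a first (control)
#' reactor fed fresh medium, whose outflow feeds a second (experimental)
#' reactor, both at the same dilution rate. Cell balance:
#' \deqn{dX_1/d\tau = X_1(\mu_1 - D)}
#' \deqn{dX_2/d\tau = D X_1 + \mu_2 X_2 - D X_2}
#' At chemostat steady state in reactor 1, \eqn{\mu_1 = D} and \eqn{X_1} is
#' constant; the second reactor then has the closed-form solution implemented
#' in [analytic_X2()].
#'
#' @param D Dilution rate (day^-1), must be positive. Reciprocal of the
#'   hydraulic retention time.
#' @param mu1 Specific growth rate in reactor 1 (day^-1). Defaults to `D`
#'   (steady-state chemostat).
#' @param mu2 Specific growth rate in reactor 2 (day^-1). May be negative:
#'   net cell death under toxic loading.
#' @param X1_0 Initial (or steady) cell concentration in reactor 1
#'   (1e7 cells/mL), non-negative.
#' @param X2_0 Initial cell concentration in reactor 2 (1e7 cells/mL),
#'   non-negative.
#' @return An object of class `cascade_params` (a named list).
#' @examples
#' cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
#' @export
cascade_params <- function(D, mu1 = D, mu2 = 0, X1_0 = 100, X2_0 = X1_0) {
  for (nm in c("D", "mu1", "mu2", "X1_0", "X2_0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (D <= 0) stop("dilution rate 'D' must be positive", call. = FALSE)
  if (X1_0 < 0 || X2_0 < 0) {
    stop("initial cell concentrations must be non-negative", call. = FALSE)
  }
  structure(list(D = D, mu1 = mu1, mu2 = mu2, X1_0 = X1_0, X2_0 = X2_0),
            class = "cascade_params")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat("Cascade chemostat parameters\n")
  cat(sprintf("  D    = %g /day  (retention time %.3g days)\n", x$D, 1 / x$D))
  cat(sprintf("  mu1  = %g /day, mu2 = %g /day\n", x$mu1, x$mu2))
  cat(sprintf("  X1_0 = %g, X2_0 = %g  (1e7 cells/mL)\n", x$X1_0, x$X2_0))
  cat(sprintf("  regime: %s\n", classify_regime(x)))
  invisible(x)
}

as_cascade_params <- function(params) {
  if (inherits(params, "cascade_params")) return(params)
  do.call(cascade_params, as.list(params))
}

#' Right-hand side of the cascade cell balance
#'
#' Evaluates the time derivatives of both reactor cell concentrations.
#'
#' @param X1,X2 Cell concentrations (1e7 cells/mL), non-negative.
#' @param params A [cascade_params()] object.
#' @return Numeric vector `c(dX1, dX2)` (1e7 cells/mL/day).
#' @examples
#' p <- cascade_params(D = 0.2, mu2 = -1.0, X1_0 = 200, X2_0 = 50)
#' cascade_rhs(200, 50, p)  # c(0, -20)
#' @export
cascade_rhs <- function(X1, X2, params) {
  params <- as_cascade_params(params)
  if (X1 < 0 || X2 < 0) {
    stop("cell concentrations must be non-negative", call. = FALSE)
  }
  c(dX1 = X1 * (params$mu1 - params$D),
    dX2 = params$D * X1 + params$mu2 * X2 - params$D * X2)
}

# Second-reactor solution with reactor 1 held at steady state; handles the
# mu2 == D degenerate case (linear growth) that the exported closed form
# refuses.  Used by the fitter and the simulator's cross-checks.
x2_solution <- function(tau, D, mu2, X1, X2_0, tol = 1e-12) {
  if (abs(mu2 - D) <= tol) {
    return(X2_0 + D * X1 * tau)
  }
  xss <- D * X1 / (D - mu2)
  xss + (X2_0 - xss) * exp((mu2 - D) * tau)
}

#' Closed-form cell concentration in the second reactor
#'
#' With reactor 1 at chemostat steady state (constant `X1_0`), the second
#' reactor's balance is linear and solves to
#' \deqn{X_2(\tau) = \frac{D X_1}{D - \mu_2} + C e^{(\mu_2 - D)\tau},}
#' with the integration constant fixed by \eqn{X_2(0) = X_{2,0}}. The case
#' \eqn{\mu_2 = D} is singular (the particular solution diverges) and is
#' refused here; it grows linearly as \eqn{X_2(\tau) = X_{2,0} + D X_1 \tau},
#' which [simulate_cascade()] handles.
#'
#' @param tau Time since the start of the balance (days); vectorised.
#' @param params A [cascade_params()] object with `mu2 != D`.
#' @return Cell concentration(s) in reactor 2 (1e7 cells/mL).
#' @examples
#' p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
#' analytic_X2(c(0, 10, 30), p)
#' @export
analytic_X2 <- function(tau, params) {
  params <- as_cascade_params(params)
  if (abs(params$mu2 - params$D) <= 1e-12) {
    stop("mu2 == D is a degenerate (linear-growth) case: X2 grows as ",
         "X2_0 + D*X1*tau; use simulate_cascade() for this regime",
         call. = FALSE)
  }
  if (any(tau < 0)) stop("'tau' must be non-negative", call. = FALSE)
  x2_solution(tau, params$D, params$mu2, params$X1_0, params$X2_0, tol = 0)
}

#' Steady-state cell concentration in the second reactor
#'
#' For `mu2 < D` the exponential term decays and reactor 2 settles at
#' \eqn{D X_1 / (D - \mu_2)}. For `mu2 >= D` there is no finite steady
#' state (exponential or linear growth) and `Inf` is returned with the
#' attribute `diverges = TRUE`.
#'
#' @inheritParams analytic_X2
#' @return A single concentration (1e7 cells/mL), or `Inf` (attribute
#'   `diverges = TRUE`) when the population grows without bound.
#' @examples
#' steady_state_X2(cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200))
#' steady_state_X2(cascade_params(D = 0.2, mu2 = 0, X1_0 = 200))  # == X1_0
#' @export
steady_state_X2 <- function(params) {
  params <- as_cascade_params(params)
  if (params$mu2 >= params$D) {
    return(structure(Inf, diverges = TRUE))
  }
  if (params$mu2 == 0) return(params$X1_0)  # X1 exactly, no roundoff
  params$D * params$X1_0 / (params$D - params$mu2)
}

#' Classify the long-run growth regime of the second reactor
#'
#' The long-term behaviour of \eqn{X_2} relative to the steady first-reactor
#' concentration \eqn{X_1} is fully determined by the sign of \eqn{\mu_2}
#' relative to 0 and to the dilution rate:
#' \itemize{
#'   \item `mu2 > D`: `EXPONENTIAL_GROWTH` — unbounded exponential increase;
#'   \item `D > mu2 > 0`: `STABILIZE_ABOVE_X1` — finite plateau above `X1`;
#'   \item `mu2 == 0`: `EQUAL_X1` — `X2` converges to `X1` exactly;
#'   \item `mu2 < 0`: `BELOW_X1` — only net cell death can hold the second
#'     reactor below the first;
#'   \item `mu2 == D`: `LINEAR_GROWTH` — the singular boundary case.
#' }
#' Boundary comparisons use an absolute tolerance of 1e-12.
#'
#' @inheritParams analytic_X2
#' @return A single character label.
#' @examples
#' classify_regime(cascade_params(D = 0.2, mu2 = 0.1))   # STABILIZE_ABOVE_X1
#' classify_regime(cascade_params(D = 0.2, mu2 = -1.07)) # BELOW_X1
#' @export
classify_regime <- function(params) {
  params <- as_cascade_params(params)
  tol <- 1e-12
  mu2 <- params$mu2
  D <- params$D
  if (abs(mu2 - D) <= tol) return("LINEAR_GROWTH")
  if (abs(mu2) <= tol) return("EQUAL_X1")
  if (mu2 > D) return("EXPONENTIAL_GROWTH")
  if (mu2 > 0) return("STABILIZE_ABOVE_X1")
  "BELOW_X1"
}

#' Simulate the cascade cell balance numerically
#'
#' Integrates the cascade system with deSolve's `lsoda` (adaptive,
#' stiff-capable; the system stiffens when `mu2` is strongly negative),
#' rtol 1e-8 / atol 1e-10. By default reactor 1 is held at steady state
#' (`X1` constant, the balance the closed form assumes); with
#' `steady_state = FALSE` both equations are integrated so transient `X1`
#' (e.g. `mu1 != D`) can be explored.
#'
#' @inheritParams analytic_X2
#' @param times Strictly increasing time grid (days) starting at 0.
#' @param steady_state Hold `X1` constant at `X1_0`? Default `TRUE`.
#' @return A `cascade_trajectory`: a data.frame with columns `time_days`,
#'   `X1`, `X2`. Concentrations are floored at 0; if flooring was needed the
#'   attribute `floored` is `TRUE`.
#' @examples
#' p <- cascade_params(D = 0.2, mu2 = -1.07, X1_0 = 200, X2_0 = 200)
#' traj <- simulate_cascade(p, times = seq(0, 30, by = 0.5))
#' tail(traj, 3)
#' @export
simulate_cascade <- function(params, times, steady_state = TRUE) {
  params <- as_cascade_params(params)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing with at least two points",
         call. = FALSE)
  }
  if (times[1L] != 0) stop("'times' must start at 0", call. = FALSE)

  rhs <- function(t, y, parms) {
    dX1 <- if (steady_state) 0 else y[1L] * (parms$mu1 - parms$D)
    dX2 <- parms$D * y[1L] + (parms$mu2 - parms$D) * y[2L]
    list(c(dX1, dX2))
  }
  y0 <- c(X1 = params$X1_0, X2 = params$X2_0)
  out <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = params,
                          method = "lsoda", rtol = 1e-8, atol = 1e-10),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    stop("cascade integration failed for parameters D=", params$D,
         ", mu1=", params$mu1, ", mu2=", params$mu2,
         ", X1_0=", params$X1_0, ", X2_0=", params$X2_0, call. = FALSE)
  }
  floored <- any(out[, "X1"] < 0) || any(out[, "X2"] < 0)
  traj <- data.frame(time_days = out[, "time"],
                     X1 = pmax(out[, "X1"], 0),
                     X2 = pmax(out[, "X2"], 0))
  class(traj) <- c("cascade_trajectory", "data.frame")
  attr(traj, "floored") <- floored
  attr(traj, "params") <- params
  traj
}

#' Write / read a cascade trajectory as CSV
#'
#' Plain CSV with columns `time_days`, `X1`, `X2`.
#'
#' @param traj A `cascade_trajectory` (or compatible data.frame).
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a `cascade_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(c("time_days", "X1", "X2") %in% names(traj)))
  utils::write.csv(as.data.frame(traj)[c("time_days", "X1", "X2")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_days", "X1", "X2") %in% names(df)))
  if (any(diff(df$time_days) <= 0)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("cascade_trajectory", "data.frame")
  df
}
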