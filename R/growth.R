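#' Cell-count time series for one reactor
#'
#' @param times Sampling times (days), strictly increasing, >= 3 points.
#' @param counts Total cell counts (1e7 cells/mL), non-negative.
#' @param reactor `"control"` or `"experimental"`.
#' @return A data.frame of class `cell_count_series` with columns
#'   `time_days`, `count`, and attribute `reactor`.
#' @export
cell_count_series <- function(times, counts,
                              reactor = c("control", "experimental")) {
  reactor <- match.arg(reactor)
  if (length(times) != length(counts)) {
    stop("'times' and 'counts' must have the same length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("at least 3 points are needed for derivative estimation",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- data.frame(time_days = as.numeric(times), count = as.numeric(counts))
  attr(out, "reactor") <- reactor
  class(out) <- c("cell_count_series", "data.frame")
  out
}

# First derivative on a (possibly irregular) grid: three-point nonuniform
# central differences at interior points, two-point one-sided at the ends.
fd_derivative <- function(t, y) {
  n <- length(t)
  stopifnot(n >= 3L, length(y) == n)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  h1 <- t[i] - t[i - 1L]
  h2 <- t[i + 1L] - t[i]
  d[i] <- (-h2 / (h1 * (h1 + h2))) * y[i - 1L] +
    ((h2 - h1) / (h1 * h2)) * y[i] +
    (h1 / (h2 * (h1 + h2))) * y[i + 1L]
  d
}

# Linear interpolation of the control series onto target times; points
# outside the control's span are dropped (no extrapolation).
interp_control <- function(control, times) {
  keep <- times >= min(control$time_days) & times <= max(control$time_days)
  list(times = times[keep],
       counts = stats::approx(control$time_days, control$count,
                              xout = times[keep])$y,
       keep = keep)
}

#' Estimate the first-reactor specific growth rate from counts
#'
#' Rearranges the first-reactor balance `dX1/dt = X1 (mu1 - D)` to
#' `mu1(t) = D + X1'(t)/X1(t)`, with the derivative from finite differences
#' (three-point nonuniform central at interior points, one-sided at the
#' ends). At chemostat steady state the series is flat and `mu1 = D`.
#'
#' @param series_control A [cell_count_series()] for the control reactor;
#'   counts must be strictly positive.
#' @param D Dilution rate (day^-1).
#' @return A data.frame with columns `time_days` and `mu1` (day^-1).
#' @examples
#' s <- cell_count_series(seq(0, 10, 2), rep(200, 6))
#' estimate_mu1(s, D = 0.2)  # mu1 == 0.2 everywhere
#' @export
estimate_mu1 <- function(series_control, D) {
  if (any(series_control$count <= 0)) {
    stop("counts must be strictly positive (log-derivative requires X1 > 0)",
         call. = FALSE)
  }
  dX <- fd_derivative(series_control$time_days, series_control$count)
  data.frame(time_days = series_control$time_days,
             mu1 = D + dX / series_control$count)
}

#' Pointwise second-reactor growth rate from paired count series
#'
#' Rearranges the second-reactor balance
#' `dX2/dt = D X1 + (mu2 - D) X2` to
#' \deqn{\mu_2(t) = \frac{X_2'(t) - D X_1(t) + D X_2(t)}{X_2(t)},}
#' with `X2'` from finite differences and the control series linearly
#' interpolated onto the experimental sampling times (no extrapolation:
#' experimental points outside the control's time span are dropped). Zero
#' experimental counts are floored at half the smallest positive count,
#' with a warning, to keep the division defined.
#'
#' @param series_control,series_exp [cell_count_series()] objects for the
#'   control (reactor 1) and experimental (reactor 2) reactors.
#' @param D Dilution rate (day^-1).
#' @return A data.frame with columns `time_days` and `mu2` (day^-1).
#' @export
estimate_mu2_pointwise <- function(series_control, series_exp, D) {
  ic <- interp_control(series_control, series_exp$time_days)
  if (sum(ic$keep) < 3L) {
    stop("control and experimental series overlap in fewer than 3 points",
         call. = FALSE)
  }
  x2 <- series_exp$count[ic$keep]
  if (any(x2 == 0)) {
    floor_val <- min(x2[x2 > 0]) / 2
    if (!is.finite(floor_val)) {
      stop("experimental counts are all zero; mu2 is undefined", call. = FALSE)
    }
    warning("zero experimental counts floored at ", signif(floor_val, 3),
            " (half the smallest positive count)", call. = FALSE)
    x2[x2 == 0] <- floor_val
  }
  dX2 <- fd_derivative(ic$times, x2)
  data.frame(time_days = ic$times,
             mu2 = (dX2 - D * ic$counts + D * x2) / x2)
}

#' Fit a constant second-reactor growth rate by least squares
#'
#' Assumes reactor 1 near steady state (X1 taken as the mean of the
#' interpolated control counts) and fits the closed-form second-reactor
#' solution to the observed experimental counts by minimising the sum of
#' squared errors over `mu2` (golden-section/parabolic search on
#' `interval`). Uncertainty comes from a seeded residual bootstrap:
#' residuals are resampled with replacement onto the fitted curve and the
#' fit repeated; the half-width is 1.96 times the bootstrap standard
#' deviation.
#'
#' @inheritParams estimate_mu2_pointwise
#' @param n_boot Number of bootstrap resamples (default 200; 0 disables the
#'   uncertainty estimate).
#' @param seed Integer seed for the bootstrap.
#' @param interval Search interval for `mu2` (day^-1).
#' @return A list with elements `mu2`, `half_width`, `X1`, `X2_0`, `sse`,
#'   `n`, and `boot` (the bootstrap draws, if any).
#' @examples
#' p <- cascade_params(D = 0.2, mu2 = -0.5, X1_0 = 200, X2_0 = 200)
#' tt <- seq(0, 33, 3)
#' ctrl <- cell_count_series(tt, rep(200, length(tt)))
#' exp_ <- cell_count_series(tt, analytic_X2(tt, p), "experimental")
#' fit_mu2_constant(ctrl, exp_, D = 0.2, n_boot = 0)$mu2
#' @export
fit_mu2_constant <- function(series_control, series_exp, D,
                             n_boot = 200, seed = 1,
                             interval = c(-5, 3)) {
  if (nrow(series_exp) < 4L) {
    stop("at least 4 experimental points are needed for the global fit",
         call. = FALSE)
  }
  ic <- interp_control(series_control, series_exp$time_days)
  if (sum(ic$keep) < 4L) {
    stop("control and experimental series overlap in fewer than 4 points",
         call. = FALSE)
  }
  tt <- ic$times - ic$times[1L]
  x2 <- series_exp$count[ic$keep]
  X1 <- mean(ic$counts)
  X2_0 <- x2[1L]

  sse_of <- function(mu2, obs) {
    pred <- x2_solution(tt, D, mu2, X1, X2_0)
    sum((obs - pred)^2)
  }
  fit_once <- function(obs) {
    opt <- stats::optimize(sse_of, interval = interval, obs = obs,
                           tol = 1e-9)
    opt$minimum
  }
  mu2_hat <- fit_once(x2)
  opt_sse <- sse_of(mu2_hat, x2)
  if (!is.finite(mu2_hat) || !is.finite(opt_sse)) {
    stop("mu2 fit failed to converge (D=", D, ", X1=", signif(X1, 4),
         ", n=", length(x2), ")", call. = FALSE)
  }

  boot <- NULL
  half_width <- NA_real_
  if (n_boot > 0) {
    fitted <- x2_solution(tt, D, mu2_hat, X1, X2_0)
    res <- x2 - fitted
    boot <- numeric(n_boot)
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (b in seq_len(n_boot)) {
      obs_b <- fitted + sample(res, length(res), replace = TRUE)
      boot[b] <- fit_once(obs_b)
    }
    half_width <- 1.96 * stats::sd(boot)
  }
  list(mu2 = mu2_hat, half_width = half_width, X1 = X1, X2_0 = X2_0,
       sse = opt_sse, n = length(x2), boot = boot)
}

# Scoped RNG handling so seeded routines do not clobber the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
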