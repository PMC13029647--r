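#' Measured time series for one reactor run
#'
#' Validating constructor for the standard monitoring table of a bioleaching
#' run: pH, redox potential, iron speciation, cell counts, and optional
#' dissolved-metal columns.
#'
#' @param times Sampling times (days), strictly increasing.
#' @param pH,Eh_mV,fe2_gL,fe3_gL,fetot_gL,cells_1e7_mL Optional numeric
#'   columns (same length as `times`); concentrations must be non-negative.
#' @param ... Additional numeric columns (e.g. `cu_gL`, `ni_gL`).
#' @param fe_tol Tolerance (g/L) for the consistency check
#'   `fetot ~ fe2 + fe3` when all three are present; violations warn, they
#'   do not reject. Default 0.2.
#' @return A data.frame of class `reactor_series` with a `time_days` column
#'   plus whichever variables were supplied.
#' @export
reactor_series <- function(times, pH = NULL, Eh_mV = NULL, fe2_gL = NULL,
                           fe3_gL = NULL, fetot_gL = NULL,
                           cells_1e7_mL = NULL, ..., fe_tol = 0.2) {
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  cols <- list(pH = pH, Eh_mV = Eh_mV, fe2_gL = fe2_gL, fe3_gL = fe3_gL,
               fetot_gL = fetot_gL, cells_1e7_mL = cells_1e7_mL)
  cols <- c(cols[!vapply(cols, is.null, logical(1))], list(...))
  out <- data.frame(time_days = as.numeric(times))
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != length(times)) {
      stop("column '", nm, "' length does not match 'times'", call. = FALSE)
    }
    if (nm != "pH" && nm != "Eh_mV" && any(v < 0, na.rm = TRUE)) {
      stop("column '", nm, "' has negative concentrations", call. = FALSE)
    }
    out[[nm]] <- as.numeric(v)
  }
  if (all(c("fe2_gL", "fe3_gL", "fetot_gL") %in% names(out))) {
    gap <- abs(out$fetot_gL - (out$fe2_gL + out$fe3_gL))
    if (any(gap > fe_tol, na.rm = TRUE)) {
      warning("fetot_gL differs from fe2_gL + fe3_gL by up to ",
              signif(max(gap, na.rm = TRUE), 3), " g/L (tolerance ", fe_tol,
              ")", call. = FALSE)
    }
  }
  class(out) <- c("reactor_series", "data.frame")
  out
}

# Rising-crossing finder shared by the threshold metrics.  Returns the
# interpolated (or snapped) first time v reaches thr from below, NA if never.
first_rising_crossing <- function(times, v, thr, snap = FALSE,
                                  sustained = FALSE) {
  n <- length(v)
  if (v[1L] >= thr) return(times[1L])
  for (i in 2:n) {
    if (v[i] >= thr) {
      if (sustained && i < n && v[i + 1L] < thr) next
      if (snap) return(times[i])
      if (v[i] == v[i - 1L]) return(times[i])
      return(times[i - 1L] +
               (thr - v[i - 1L]) / (v[i] - v[i - 1L]) *
               (times[i] - times[i - 1L]))
    }
  }
  NA_real_
}

#' Time to first crossing of a reference threshold
#'
#' First time a monitored variable crosses a reference value (e.g. pH 1.2
#' falling, Eh 800 mV rising), located by linear interpolation between the
#' bracketing samples; a series starting at the threshold returns the first
#' sample time. With `snap = TRUE` the crossing is reported as the first
#' sample time at or past the threshold instead, matching tables reported at
#' integer sampling days.
#'
#' @param series A [reactor_series()].
#' @param variable Column name, e.g. `"pH"`, `"Eh_mV"`.
#' @param threshold Reference value.
#' @param direction `"rising"` or `"falling"`.
#' @param snap Report the next sample time instead of interpolating.
#' @return Crossing time (days), or `NA` if the threshold is never reached.
#' @examples
#' s <- reactor_series(0:12, pH = 1.6 - 0.05 * (0:12))
#' time_to_threshold(s, "pH", 1.2, "falling")  # 8
#' @export
time_to_threshold <- function(series, variable, threshold,
                              direction = c("rising", "falling"),
                              snap = FALSE) {
  direction <- match.arg(direction)
  if (!variable %in% names(series)) {
    stop("variable '", variable, "' not present in series", call. = FALSE)
  }
  v <- series[[variable]]
  thr <- threshold
  if (direction == "falling") {
    v <- -v
    thr <- -thr
  }
  first_rising_crossing(series$time_days, v, thr, snap = snap)
}

#' Time of complete (sustained) ferrous-iron oxidation
#'
#' First sampling time at which the Fe2+ concentration falls below the
#' detection limit and stays below it for every later sample. A transient
#' dip followed by a rebound does not count; the later sustained crossing
#' does.
#'
#' @param series A [reactor_series()] with an `fe2_gL` column.
#' @param lod Detection limit (g/L). Default 0.05, a practical floor for
#'   titrimetric iron determination; configurable.
#' @return Depletion time (days), or `NA` if Fe2+ never stays below `lod`.
#' @examples
#' s <- reactor_series(c(0, 6, 9, 12, 15), fe2_gL = c(0.7, 0.7, 0.3, 0, 0))
#' fe2_depletion_time(s)  # 12
#' @export
fe2_depletion_time <- function(series, lod = 0.05) {
  if (!"fe2_gL" %in% names(series)) {
    stop("series has no 'fe2_gL' column", call. = FALSE)
  }
  below <- series$fe2_gL < lod
  n <- length(below)
  # first index from which everything stays below the LOD
  sustained_from <- rev(cumprod(rev(below))) == 1
  if (!any(sustained_from)) return(NA_real_)
  series$time_days[which(sustained_from)[1L]]
}

#' Duration of the lag phase from cell counts
#'
#' Operational definition: the (interpolated) time at which the cell count
#' first exceeds `k_fold` times the initial count and remains above that
#' level at the following sample. The k-fold-sustained rule is this
#' package's own convention -- batch-culture reports rarely define the lag
#' operationally -- and `k_fold` is exposed so other conventions can be
#' applied.
#'
#' @param series A [reactor_series()] with a `cells_1e7_mL` column whose
#'   first count is positive.
#' @param k_fold Fold increase over the initial count marking the end of the
#'   lag (default 2).
#' @param snap Report the next sample time instead of interpolating.
#' @return Lag duration (days), or `NA` if the count never sustains the
#'   k-fold increase.
#' @examples
#' s <- reactor_series(c(0, 8, 16, 20, 24), cells_1e7_mL = c(1, 1, 1, 4, 16))
#' lag_phase_duration(s)  # 17.33
#' @export
lag_phase_duration <- function(series, k_fold = 2, snap = FALSE) {
  if (!"cells_1e7_mL" %in% names(series)) {
    stop("series has no 'cells_1e7_mL' column", call. = FALSE)
  }
  x <- series$cells_1e7_mL
  if (x[1L] <= 0) stop("first cell count must be positive", call. = FALSE)
  thr <- k_fold * x[1L]
  t0 <- series$time_days[1L]
  cross <- first_rising_crossing(series$time_days, x, thr, snap = snap,
                                 sustained = TRUE)
  if (is.na(cross)) return(NA_real_)
  cross - t0
}

#' Batch-run summary metrics
#'
#' One-row summary of the standard batch-mode process indicators: time to a
#' reference pH (falling), time to a reference Eh (rising), sustained Fe2+
#' depletion time, and lag-phase duration.
#'
#' @param series A [reactor_series()].
#' @param ph_ref Reference pH (default 1.2).
#' @param eh_ref Reference Eh in mV (default 800).
#' @param lod Fe2+ detection limit in g/L (default 0.05).
#' @param k_fold Lag-phase fold threshold (default 2).
#' @param snap Snap crossings to sample times (integer-day style reporting).
#' @return A one-row data.frame with columns `t_pH`, `t_Eh`, `t_fe2_depletion`,
#'   `lag_days` (days; `NA` where not reached or the variable is absent).
#' @export
batch_metrics <- function(series, ph_ref = 1.2, eh_ref = 800, lod = 0.05,
                          k_fold = 2, snap = FALSE) {
  get_or_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  data.frame(
    t_pH = get_or_na(time_to_threshold(series, "pH", ph_ref, "falling",
                                       snap = snap)),
    t_Eh = get_or_na(time_to_threshold(series, "Eh_mV", eh_ref, "rising",
                                       snap = snap)),
    t_fe2_depletion = get_or_na(fe2_depletion_time(series, lod = lod)),
    lag_days = get_or_na(lag_phase_duration(series, k_fold = k_fold,
                                            snap = snap)))
}
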