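#' Stepwise feed schedule for the material-balance model
#'
#' A schedule of discrete feed events for a constant-volume stirred reactor:
#' at each sampling step a volume `v_added` of fresh pulp at inlet PCB
#' concentration `inlet_conc` displaces an equal volume of reactor pulp.
#'
#' @param end_day Day each step ends on (strictly increasing).
#' @param inlet_conc Inlet PCB dust concentration Y_i (g/L) for each step.
#' @param v_added Replaced volume per step (mL); recycled to length.
#' @param v_total Constant reactor volume (mL); recycled to length.
#' @return A data.frame of class `feed_schedule` with columns `end_day`,
#'   `inlet_conc`, `v_added`, `v_total`.
#' @seealso [pcb_feed_schedule()] for the packaged continuous-mode schedule.
#' @export
feed_schedule <- function(end_day, inlet_conc, v_added = 400, v_total = 1000) {
  n <- length(end_day)
  if (n == 0L) stop("schedule must have at least one step", call. = FALSE)
  sched <- data.frame(end_day = as.numeric(end_day),
                      inlet_conc = as.numeric(inlet_conc),
                      v_added = rep_len(as.numeric(v_added), n),
                      v_total = rep_len(as.numeric(v_total), n))
  if (any(diff(sched$end_day) <= 0)) {
    stop("'end_day' must be strictly increasing", call. = FALSE)
  }
  if (any(sched$inlet_conc < 0)) {
    stop("inlet concentrations must be non-negative", call. = FALSE)
  }
  if (any(sched$v_added <= 0) || any(sched$v_added > sched$v_total)) {
    stop("each step needs 0 < v_added <= v_total", call. = FALSE)
  }
  class(sched) <- c("feed_schedule", "data.frame")
  sched
}

#' One material-balance dilution step
#'
#' Mixing balance for a constant-volume reactor where `v_added` mL of pulp at
#' concentration `Yi` displaces an equal volume of reactor pulp at
#' concentration `Xi`:
#' \deqn{X_{i+1} = \frac{X_i (V_{total} - V_{added}) + Y_i V_{added}}{V_{total}}}
#' The output always lies between `Xi` and `Yi` (convex combination).
#'
#' @param Xi Current in-reactor PCB concentration (g/L).
#' @param Yi Inlet (added pulp) PCB concentration (g/L).
#' @param v_added Replaced volume (mL), `0 < v_added <= v_total`.
#' @param v_total Reactor volume (mL).
#' @return The post-step concentration (g/L).
#' @examples
#' dilution_step(5, 12.5, 400, 1000)  # 8.0
#' @export
dilution_step <- function(Xi, Yi, v_added, v_total) {
  if (Xi < 0 || Yi < 0) stop("concentrations must be non-negative", call. = FALSE)
  if (v_added <= 0 || v_total <= 0 || v_added > v_total) {
    stop("need 0 < v_added <= v_total", call. = FALSE)
  }
  (Xi * (v_total - v_added) + Yi * v_added) / v_total
}

#' Run a feed schedule through the dilution recursion
#'
#' Applies [dilution_step()] once per schedule entry, carrying full floating
#' point precision between steps (round only when reporting).
#'
#' @param X0 In-reactor PCB concentration (g/L) before the first step.
#' @param schedule A [feed_schedule()].
#' @return A data.frame of class `dilution_series` with columns `day` and
#'   `conc` (g/L). The first row is day 0 at `X0`.
#' @examples
#' run_schedule(5, pcb_feed_schedule())
#' @export
run_schedule <- function(X0, schedule) {
  if (!inherits(schedule, "feed_schedule")) schedule <- feed_schedule(
    schedule$end_day, schedule$inlet_conc, schedule$v_added, schedule$v_total)
  if (!is.numeric(X0) || length(X0) != 1L || X0 < 0) {
    stop("'X0' must be a single non-negative number", call. = FALSE)
  }
  conc <- numeric(nrow(schedule))
  x <- X0
  for (i in seq_len(nrow(schedule))) {
    x <- dilution_step(x, schedule$inlet_conc[i],
                       schedule$v_added[i], schedule$v_total[i])
    conc[i] <- x
  }
  out <- data.frame(day = c(0, schedule$end_day), conc = c(X0, conc))
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' Limit of the dilution recursion under a constant feed
#'
#' With a constant inlet concentration `Yi` and a fixed replaced fraction
#' `f = v_added / v_total`, the recursion contracts geometrically:
#' `|X_n - Yi| = |X0 - Yi| (1 - f)^n`. The limit is `Yi`, and the number of
#' steps to come within `eps` of it is `ceil(log(eps / |X0 - Yi|) / log(1 - f))`
#' (one step when `f = 1`, full replacement).
#'
#' @param X0 Starting concentration (g/L).
#' @param Yi Constant inlet concentration (g/L).
#' @param f Replaced volume fraction per step, in (0, 1].
#' @param eps Convergence tolerance (g/L), default 0.1.
#' @return A list with `limit` (g/L) and `steps` (integer).
#' @examples
#' limit_concentration(5, 12.5, f = 0.4, eps = 0.1)  # steps = 9
#' @export
limit_concentration <- function(X0, Yi, f, eps = 0.1) {
  if (f <= 0 || f > 1) stop("'f' must be in (0, 1]", call. = FALSE)
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  gap <- abs(X0 - Yi)
  steps <- if (f == 1 || gap <= eps) {
    if (gap <= eps) 0L else 1L
  } else {
    as.integer(ceiling(log(eps / gap) / log(1 - f)))
  }
  list(limit = Yi, steps = steps)
}

#' The continuous-mode PCB feed schedule of the cascade experiment
#'
#' The stepwise feed programme of the published continuous-mode run: inlet
#' pulp at 5 g/L PCB dust through day 11, 12.5 g/L for the steps ending on
#' days 14-22, and 37.5 g/L for the steps ending on days 25-34, each step
#' replacing 400 mL of a 1000 mL working volume. The step ending on day 22
#' still carries the old 12.5 g/L feed: the feed switch takes effect from
#' the following step, the only reading consistent with the published
#' in-reactor concentrations. With a 5-day retention time (D = 0.2/day) and
#' ~2-day sampling, 400 mL per step is the per-step replacement that
#' reproduces the published concentration series; the same 400 mL applies to
#' the occasional 3-day intervals.
#'
#' @return A [feed_schedule()] of 15 steps ending on days
#'   3,5,7,9,11,14,16,18,20,22,25,27,29,31,34.
#' @examples
#' ser <- run_schedule(5, pcb_feed_schedule())
#' round(ser$conc[ser$day %in% c(16, 22, 34)], 1)  # 9.8 11.9 35.5
#' @export
pcb_feed_schedule <- function() {
  feed_schedule(
    end_day = c(3, 5, 7, 9, 11, 14, 16, 18, 20, 22, 25, 27, 29, 31, 34),
    inlet_conc = c(rep(5, 5), rep(12.5, 5), rep(37.5, 5)),
    v_added = 400, v_total = 1000)
}

#' Published in-reactor PCB dust concentrations, continuous mode
#'
#' The in-reactor PCB dust concentrations reported for the continuous-mode
#' cascade run (g/L, one decimal), as reproduced by
#' `run_schedule(5, pcb_feed_schedule())`. Useful as a regression target and
#' for encoding exposure at sampling days.
#'
#' @return A data.frame with columns `day` and `conc_gL`.
#' @export
pcb_reference_series <- function() {
  data.frame(
    day = c(0, 3, 5, 7, 9, 11, 14, 16, 18, 20, 22, 25, 27, 29, 31, 34),
    conc_gL = c(5, 5, 5, 5, 5, 5, 8, 9.8, 10.9, 11.5, 11.9,
                22.2, 28.3, 32.0, 34.2, 35.5))
}

#' Read / write a feed schedule as CSV
#'
#' Columns: `end_day`, `inlet_conc_g_per_L`, `v_added_mL`, `v_total_mL`.
#'
#' @param path File path.
#' @param schedule A [feed_schedule()].
#' @return `read_schedule()` returns a `feed_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("end_day", "inlet_conc_g_per_L", "v_added_mL", "v_total_mL")
  if (!all(need %in% names(df))) {
    stop("schedule file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  feed_schedule(df$end_day, df$inlet_conc_g_per_L, df$v_added_mL, df$v_total_mL)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  df <- data.frame(end_day = schedule$end_day,
                   inlet_conc_g_per_L = schedule$inlet_conc,
                   v_added_mL = schedule$v_added,
                   v_total_mL = schedule$v_total)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
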