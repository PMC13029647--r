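#' Read and write reactor time series
#'
#' CSV interchange for [reactor_series()] tables. Expected columns:
#' `time_days`, then any of `pH`, `Eh_mV`, `fe2_gL`, `fe3_gL`, `fetot_gL`,
#' `cells_1e7_mL` plus extra numeric columns (e.g. `cu_gL`, `ni_gL`), which
#' are preserved. Validation on read: strictly increasing time (the
#' offending row is named), non-negative concentrations; a
#' `fetot != fe2 + fe3` discrepancy beyond 0.2 g/L warns but does not
#' reject.
#'
#' @param path CSV file path.
#' @param series A [reactor_series()] (or compatible data.frame).
#' @return `read_timeseries()` returns a `reactor_series`;
#'   `write_timeseries()` returns `path` invisibly.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_days" %in% names(df)) {
    stop("file has no 'time_days' column: ", path, call. = FALSE)
  }
  bad <- which(diff(df$time_days) <= 0)
  if (length(bad) > 0L) {
    stop("non-increasing time at row ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  args <- c(list(times = df$time_days),
            df[setdiff(names(df), "time_days")])
  do.call(reactor_series, args)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read and write genus abundance tables
#'
#' Wide CSV: metadata columns `sample_id`, `day`, `reactor`, `pcb_gL` (any
#' may be absent except at least one genus column), then one numeric column
#' per genus with relative abundance in percent. The [abundance_table()]
#' validation applies on read: abundances outside [0, 100] or per-sample
#' totals above 100 are rejected with row diagnostics; partial tables
#' without an `Other` column and totals below 100 are accepted.
#'
#' @param path CSV file path.
#' @param table An [abundance_table()].
#' @return `read_abundance()` returns an `abundance_table`;
#'   `write_abundance()` returns `path` invisibly.
#' @export
read_abundance <- function(path) {
  abundance_table(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_abundance
#' @export
write_abundance <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write a full synthetic data bundle to a directory
#'
#' Materialises the output of [generate_continuous_cascade()] as CSV files
#' (`control.csv`, `experimental.csv`, `counts_control.csv`,
#' `counts_exp.csv`, `dilution.csv`, `abundance.csv`) so the pipeline can be
#' exercised from files alone.
#'
#' @param bundle Output of [generate_continuous_cascade()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_timeseries(bundle$control, file.path(dir, "control.csv"))
  write_timeseries(bundle$experimental, file.path(dir, "experimental.csv"))
  for (nm in c("counts_control", "counts_exp")) {
    df <- data.frame(time_days = bundle[[nm]]$time_days,
                     count_1e7_per_mL = bundle[[nm]]$count,
                     reactor = attr(bundle[[nm]], "reactor"))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(bundle$dilution),
                   file.path(dir, "dilution.csv"), row.names = FALSE)
  write_abundance(bundle$abundance, file.path(dir, "abundance.csv"))
  invisible(dir)
}

#' Read a cell-count series from CSV
#'
#' Columns: `time_days`, `count_1e7_per_mL`, `reactor`.
#'
#' @param path CSV file path.
#' @return A [cell_count_series()].
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_days", "count_1e7_per_mL", "reactor")
  if (!all(need %in% names(df))) {
    stop("count file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cell_count_series(df$time_days, df$count_1e7_per_mL,
                    reactor = df$reactor[1L])
}

#' Run the full co-bioleaching analysis pipeline
#'
#' Executes the analysis stages in order on the inputs named in `config`:
#' dilution recursion, exposure encoding, growth-rate estimation, leach
#' yields, batch metrics, and community correlation. Stages whose inputs are
#' absent from the config are marked `"skipped"`; a failing stage aborts
#' with the stage name and cause. Inputs may be given as file paths or as
#' in-memory objects.
#'
#' @param config A named list: `X0_pcb` (g/L), `schedule` (path or
#'   [feed_schedule()]), `D` (day^-1), `counts_control` / `counts_exp`
#'   (paths or [cell_count_series()]), optional `experimental` (path or
#'   [reactor_series()]) for batch metrics, optional `abundance` (path or
#'   [abundance_table()]), optional `yields` (data.frame with columns
#'   `metal`, `m_le_g`, `m_lc_g`, `day`), optional `v_total_L` (default 1),
#'   optional `exposure_mode` (default "concentration"), optional `seed`
#'   (default 1), optional `out_dir` to write per-stage CSVs.
#' @return A list with one element per stage (`dilution`, `exposure`,
#'   `growth`, `yields`, `metrics`, `correlations`) plus `params`, the fully
#'   resolved parameter set used.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  cfg$v_total_L <- cfg$v_total_L %||% 1
  cfg$exposure_mode <- cfg$exposure_mode %||% "concentration"
  cfg$seed <- cfg$seed %||% 1L
  report <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  load_as <- function(x, reader) if (is.character(x)) reader(x) else x

  sched <- stage("dilution", {
    if (is.null(cfg$schedule) || is.null(cfg$X0_pcb)) {
      stop("config needs 'schedule' and 'X0_pcb'")
    }
    load_as(cfg$schedule, read_schedule)
  })
  report$dilution <- stage("dilution", run_schedule(cfg$X0_pcb, sched))

  abund <- if (!is.null(cfg$abundance)) {
    stage("exposure", load_as(cfg$abundance, read_abundance))
  }
  report$exposure <- if (is.null(abund)) "skipped" else {
    stage("exposure",
          encode_exposure(abund, report$dilution, cfg$exposure_mode))
  }

  report$growth <- if (is.null(cfg$counts_control) ||
                       is.null(cfg$counts_exp)) "skipped" else {
    stage("growth", {
      ctrl <- load_as(cfg$counts_control, read_counts)
      expd <- load_as(cfg$counts_exp, read_counts)
      list(mu1 = estimate_mu1(ctrl, cfg$D),
           mu2_pointwise = estimate_mu2_pointwise(ctrl, expd, cfg$D),
           mu2_fit = fit_mu2_constant(ctrl, expd, cfg$D, seed = cfg$seed))
    })
  }

  report$yields <- if (is.null(cfg$yields)) "skipped" else {
    stage("yields", {
      comp <- pcb_composition()
      do.call(rbind, lapply(seq_len(nrow(cfg$yields)), function(i) {
        row <- cfg$yields[i, ]
        xi <- report$dilution$conc[max(which(report$dilution$day <= row$day))]
        y <- leach_yield(row$m_le_g, row$m_lc_g, xi, cfg$v_total_L,
                         comp[[row$metal]])
        data.frame(metal = row$metal, day = row$day, xi_gL = xi,
                   yield_pct = y$yield_pct, in_range = y$in_range)
      }))
    })
  }

  report$metrics <- if (is.null(cfg$experimental)) "skipped" else {
    stage("metrics",
          batch_metrics(load_as(cfg$experimental, read_timeseries)))
  }

  report$correlations <- if (is.null(abund)) "skipped" else {
    stage("correlations",
          correlate_genera(abund, mode = cfg$exposure_mode,
                           exposure = report$exposure))
  }

  report$params <- cfg[setdiff(names(cfg), c("counts_control", "counts_exp",
                                             "experimental", "abundance",
                                             "schedule"))]
  report$params$schedule <- as.data.frame(sched)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report$dilution),
                     file.path(cfg$out_dir, "dilution.csv"),
                     row.names = FALSE)
    if (is.data.frame(report$yields)) {
      utils::write.csv(report$yields, file.path(cfg$out_dir, "yields.csv"),
                       row.names = FALSE)
    }
    if (is.data.frame(report$correlations)) {
      utils::write.csv(report$correlations,
                       file.path(cfg$out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    if (is.data.frame(report$metrics)) {
      utils::write.csv(report$metrics,
                       file.path(cfg$out_dir, "metrics.csv"),
                       row.names = FALSE)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
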