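#' Genus relative-abundance table with sample metadata
#'
#' Wide table: one row per sample, metadata columns (`sample_id`, `day`,
#' `reactor`, `pcb_gL`) plus one numeric column per genus holding relative
#' abundance in percent. Validation: every abundance in [0, 100]; per-sample
#' totals must not exceed 100 (plus a small rounding allowance), and when an
#' `Other` column is present they must lie within 1 of 100. Partial tables
#' (no `Other`, totals below 100) are accepted.
#'
#' @param df A data.frame with the metadata columns above and genus columns.
#' @param meta_cols Metadata column names (default
#'   `c("sample_id", "day", "reactor", "pcb_gL")`); the rest are genera.
#' @return `df` with class `abundance_table` and attribute `genera`.
#' @export
abundance_table <- function(df,
                            meta_cols = c("sample_id", "day", "reactor",
                                          "pcb_gL")) {
  meta_cols <- intersect(meta_cols, names(df))
  genera <- setdiff(names(df), meta_cols)
  if (length(genera) == 0L) stop("no genus columns found", call. = FALSE)
  ab <- as.matrix(df[genera])
  if (!is.numeric(ab)) stop("genus columns must be numeric", call. = FALSE)
  bad <- which(ab < 0 | ab > 100, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("abundances outside [0, 100] at row ", bad[1L, 1L], ", genus '",
         genera[bad[1L, 2L]], "'", call. = FALSE)
  }
  totals <- rowSums(ab)
  if (any(totals <= 0)) {
    stop("per-sample abundance total must be positive (row ",
         which(totals <= 0)[1L], ")", call. = FALSE)
  }
  if (any(totals > 100 + 0.5)) {
    stop("per-sample abundance total exceeds 100% at row ",
         which(totals > 100.5)[1L], " (total ",
         round(max(totals), 1), "%)", call. = FALSE)
  }
  if ("Other" %in% genera && any(abs(totals - 100) > 1)) {
    stop("table has an 'Other' column but row ",
         which(abs(totals - 100) > 1)[1L], " totals ",
         round(totals[which(abs(totals - 100) > 1)[1L]], 1),
         "% (must be within 1 of 100)", call. = FALSE)
  }
  attr(df, "genera") <- genera
  class(df) <- c("abundance_table", "data.frame")
  df
}

#' Genus column names of an abundance table
#' @param table An [abundance_table()].
#' @return Character vector of genus column names.
#' @export
genera <- function(table) attr(table, "genera")

#' Pearson product-moment correlation with domain checks
#'
#' Standard Pearson correlation, refusing the undefined cases explicitly
#' (fewer than 3 paired values, or a constant vector) instead of returning
#' `NA` silently.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return Correlation coefficient in [-1, 1].
#' @examples
#' pearson_r(c(1, 2, 3), c(6, 4, 2))  # -1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Encode per-sample PCB exposure
#'
#' Joins each sample's day to the in-reactor PCB concentration series (e.g.
#' the output of [run_schedule()]). Concentration mode returns the series
#' value at the sample day (exact match, or the most recent earlier step's
#' value); presence mode maps positive concentration to 1. Control-reactor
#' samples get exposure 0 regardless of day.
#'
#' @param table An [abundance_table()] with `day` and `reactor` columns.
#' @param dilution_series A `dilution_series` from [run_schedule()] (columns
#'   `day`, `conc`).
#' @param mode `"concentration"` (g/L) or `"presence"` (0/1).
#' @return Numeric exposure vector, one value per sample, with attribute
#'   `mode`.
#' @examples
#' ser <- run_schedule(5, pcb_feed_schedule())
#' tab <- abundance_table(data.frame(
#'   sample_id = c("s1", "s2"), day = c(11, 34),
#'   reactor = "experimental", Ferroplasma = c(10, 1), Leptospirillum = c(60, 70)))
#' encode_exposure(tab, ser)  # 5, 35.5
#' @export
encode_exposure <- function(table, dilution_series,
                            mode = c("concentration", "presence")) {
  mode <- match.arg(mode)
  if (!all(c("day", "reactor") %in% names(table))) {
    stop("table needs 'day' and 'reactor' columns", call. = FALSE)
  }
  lookup <- function(d) {
    idx <- which(dilution_series$day <= d)
    if (length(idx) == 0L) {
      stop("sample day ", d, " precedes the dilution series", call. = FALSE)
    }
    dilution_series$conc[max(idx)]
  }
  conc <- vapply(seq_len(nrow(table)), function(i) {
    if (identical(table$reactor[i], "control")) 0
    else lookup(table$day[i])
  }, numeric(1))
  out <- if (mode == "presence") as.numeric(conc > 0) else conc
  attr(out, "mode") <- mode
  out
}

#' Correlate genus abundances with PCB exposure
#'
#' Computes one Pearson correlation per genus between the per-sample
#' exposure (from the table's `pcb_gL` column, or supplied explicitly) and
#' that genus's relative abundance. Genera failing the correlation
#' preconditions (constant abundance, e.g. absent everywhere) are reported
#' with `defined = FALSE` rather than dropped. No multiple-testing
#' correction is applied; `p_value` (two-sided t-test) is reported only when
#' `p_values = TRUE`.
#'
#' @param table An [abundance_table()].
#' @param mode `"concentration"` or `"presence"`; used when `exposure` is
#'   derived from the `pcb_gL` column.
#' @param exposure Optional numeric exposure vector (e.g. from
#'   [encode_exposure()]); overrides the `pcb_gL` column.
#' @param p_values Also report t-based p-values? Default `FALSE`.
#' @return A data.frame with columns `genus`, `r`, `n`, `defined` (and
#'   `p_value` if requested).
#' @export
correlate_genera <- function(table, mode = c("concentration", "presence"),
                             exposure = NULL, p_values = FALSE) {
  mode <- match.arg(mode)
  if (is.null(exposure)) {
    if (!"pcb_gL" %in% names(table)) {
      stop("no 'pcb_gL' column and no 'exposure' given", call. = FALSE)
    }
    exposure <- table$pcb_gL
    if (mode == "presence") exposure <- as.numeric(exposure > 0)
  }
  if (length(exposure) != nrow(table)) {
    stop("exposure length does not match sample count", call. = FALSE)
  }
  if (nrow(table) < 3L) stop("need at least 3 samples", call. = FALSE)
  gens <- genera(table)
  rows <- lapply(gens, function(g) {
    y <- table[[g]]
    r <- tryCatch(pearson_r(exposure, y), error = function(e) NA_real_)
    out <- data.frame(genus = g, r = r, n = length(y), defined = !is.na(r))
    if (p_values) {
      out$p_value <- if (is.na(r)) NA_real_ else {
        tt <- r * sqrt((length(y) - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), df = length(y) - 2)
      }
    }
    out
  })
  do.call(rbind, rows)
}
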