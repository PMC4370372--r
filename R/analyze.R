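#' Analyse a measurement series with run chart rules
#'
#' End-to-end analysis of a real time series: builds the run chart,
#' computes its statistics, evaluates the requested rule sets and collects
#' the signal limits that applied. Accepts a CSV file (header row required;
#' values in a `value` column unless renamed via `value_col`, optional
#' `date`/label column passed through unparsed) or a data frame.
#'
#' @param x Path to a CSV file, or a data frame.
#' @param baseline Number of leading points for the median; defaults to the
#'   whole series.
#' @param rules Rule sets to apply, as in [evaluate_rules()].
#' @param value_col Name of the value column when `x` is a file or data
#'   frame (default `"value"`).
#' @param label_col Optional name of a label column (default `"date"` when
#'   present).
#' @return An object of class `run_chart_analysis`: a list with `chart`
#'   (the [run_chart()]), `stats` (one-row tibble), `verdicts` (one row per
#'   rule set) and `limits` (the [signal_limits()] used). `tidy()` returns
#'   the verdicts, `glance()` the statistics.
#' @examples
#' df <- data.frame(value = c(3, 5, 2, 7, 1, 6, 2, 8, 1, 9))
#' analyze_series(df, baseline = 10)
#' @export
analyze_series <- function(x, baseline = NULL, rules = "all",
                           value_col = "value", label_col = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("file not found: %s", x))
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a CSV path or a data frame.")
  }
  if (!value_col %in% names(x)) {
    abort(sprintf("no `%s` column in the input.", value_col))
  }
  values <- x[[value_col]]
  if (!is.numeric(values)) {
    abort(sprintf("column `%s` is not numeric.", value_col))
  }
  if (length(values) < 2) abort("need at least 2 data points.")
  label_col <- label_col %||% (if ("date" %in% names(x)) "date")
  chart <- run_chart(values, baseline = baseline)
  if (!is.null(label_col) && label_col %in% names(x)) {
    chart$data$label <- x[[label_col]]
  }
  stats <- run_stats(chart)
  structure(
    list(
      chart = chart,
      stats = stats,
      verdicts = evaluate_rules(stats, rules),
      limits = signal_limits(stats$n_useful)
    ),
    class = "run_chart_analysis"
  )
}

#' @export
print.run_chart_analysis <- function(x, ...) {
  st <- x$stats
  cat("Run chart analysis\n")
  cat(sprintf("  points: %d  baseline: %d  median: %.6g\n",
              st$n_obs, st$baseline_len, st$median))
  cat(sprintf(
    "  useful: %d  crossings: %d  runs: %d  longest run: %d  longest trend: %d\n",
    st$n_useful, st$n_crossings, st$n_runs, st$longest_run, st$longest_trend
  ))
  lim <- x$limits
  if (st$n_useful >= 1) {
    cat(sprintf(
      "  limits: longest-run UPL %d, crossings LPL %d, runs band [%d, %d]\n",
      lim$longest_run_upl, lim$crossings_lpl, lim$runs_lpl, lim$runs_upl
    ))
  } else {
    cat("  chart not evaluable: no useful observations (all points on the median)\n")
  }
  for (i in seq_len(nrow(x$verdicts))) {
    v <- x$verdicts[i, ]
    fired <- c("shift", "crossings", "runs count", "trend")[c(
      v$shift_test, v$crossings_test, v$runs_count_test, v$trend_test
    )]
    cat(sprintf(
      "  %-6s : %s%s\n", v$rule_set,
      if (!v$evaluable) "not evaluable"
      else if (v$signal) "SIGNAL" else "random variation",
      if (length(fired)) paste0(" (", paste(fired, collapse = ", "), ")") else ""
    ))
  }
  invisible(x)
}

#' @method tidy run_chart_analysis
#' @export
tidy.run_chart_analysis <- function(x, ...) x$verdicts

#' @method glance run_chart_analysis
#' @export
glance.run_chart_analysis <- function(x, ...) x$stats

#' JSON report of a run chart analysis
#'
#' Serialises the statistics, limits and verdicts of an analysis to JSON
#' with full numeric precision; the numbers are identical to those shown by
#' the print method and returned by `tidy()`/`glance()`.
#'
#' @param report A `run_chart_analysis` from [analyze_series()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "run_chart_analysis"))
  json <- jsonlite::toJSON(
    list(
      stats = report$stats,
      limits = report$limits,
      verdicts = report$verdicts
    ),
    dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
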