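#' Build a run chart from a series of measurements
#'
#' A run chart is a line graph of a quality measure over time with a
#' horizontal line at the process median. The median is computed from the
#' first `baseline` points only and then held fixed over the whole series,
#' so a later change in process level shows up as a non-random pattern of
#' points around the line rather than moving the line itself.
#'
#' @param x A numeric vector of measurements in time order, or a data frame
#'   containing them (one row per time point).
#' @param value When `x` is a data frame, the column holding the
#'   measurements (tidy-eval; default `value`).
#' @param label When `x` is a data frame, an optional column with time
#'   labels (e.g. dates), carried through to reports unparsed.
#' @param baseline Number of leading points used to compute the median.
#'   Defaults to the whole series, i.e. the ordinary run chart median.
#'
#' @return An object of class `run_chart`: a list with `data` (a tibble with
#'   columns `obs`, `value`, optionally `label`, and `position`, the
#'   above/below/on-the-median classification), `baseline_len`, and
#'   `median`.
#'
#' @examples
#' set.seed(1)
#' rc <- run_chart(rnorm(24), baseline = 12)
#' rc
#' run_stats(rc)
#' @seealso [run_stats()], [evaluate_rules()], [autoplot.run_chart()]
#' @export
run_chart <- function(x, value = value, label = NULL, baseline = NULL) {
  lab <- NULL
  if (is.data.frame(x)) {
    values <- dplyr::pull(x, {{ value }})
    lab_quo <- rlang::enquo(label)
    if (!rlang::quo_is_null(lab_quo)) lab <- dplyr::pull(x, !!lab_quo)
  } else {
    values <- x
  }
  if (!is.numeric(values) || length(values) == 0) {
    abort("`x` must supply a non-empty numeric series.")
  }
  if (anyNA(values)) abort("the value series contains missing values.")
  baseline <- baseline %||% length(values)
  if (!is.numeric(baseline) || length(baseline) != 1 || is.na(baseline) ||
      baseline < 1 || baseline > length(values) || baseline != trunc(baseline)) {
    abort(sprintf(
      "`baseline` must be a whole number between 1 and %d.", length(values)
    ))
  }
  baseline <- as.integer(baseline)
  med <- baseline_median(values, baseline)

  data <- tibble::tibble(obs = seq_along(values), value = as.double(values))
  if (!is.null(lab)) data$label <- lab
  data$position <- classify_values(values, med)

  structure(
    list(data = data, baseline_len = baseline, median = med),
    class = "run_chart"
  )
}

#' Median of the baseline segment of a series
#'
#' The sample median of the first `baseline` points (mean of the two middle
#' order statistics for an even count). This is the centre line of the run
#' chart; it is not updated as later points accrue.
#'
#' @param values Numeric series.
#' @param baseline Number of leading points to use; defaults to all.
#' @return A length-one double.
#' @examples
#' baseline_median(c(1, 2, 3, 4))        # 2.5
#' baseline_median(c(1, 2, 3, 4, 9), 4)  # still 2.5
#' @export
baseline_median <- function(values, baseline = length(values)) {
  if (length(values) == 0) abort("`values` is empty.")
  if (baseline < 1 || baseline > length(values)) {
    abort("`baseline` is out of range for this series.")
  }
  median(as.double(values[seq_len(baseline)]))
}

# Classify values against a median: "above", "below" or "on". Comparison is
# exact after rounding both sides to .rc_digits decimals.
classify_values <- function(values, med) {
  v <- round(as.double(values), .rc_digits)
  m <- round(med, .rc_digits)
  out <- rep("on", length(v))
  out[v > m] <- "above"
  out[v < m] <- "below"
  factor(out, levels = c("below", "on", "above"))
}

#' Classify each point as above, below or on the median
#'
#' Points that fall exactly on the median are "useless" observations in run
#' chart analysis: they neither extend a run nor break it, and they are
#' removed before runs and crossings are counted.
#'
#' @param chart A [run_chart()].
#' @return A factor with levels `below`, `on`, `above`, one per point.
#' @examples
#' classify_points(run_chart(c(1, 3, 2), baseline = 3))
#' @export
classify_points <- function(chart) {
  stopifnot(inherits(chart, "run_chart"))
  chart$data$position
}

#' @export
print.run_chart <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "<run_chart> %d points, baseline %d, median %.6g\n",
    n, x$baseline_len, x$median
  ))
  st <- run_stats(x)
  cat(sprintf(
    "  useful %d | crossings %d | runs %d | longest run %d | longest trend %d\n",
    st$n_useful, st$n_crossings, st$n_runs, st$longest_run, st$longest_trend
  ))
  invisible(x)
}

#' Per-point tidy view of a run chart
#'
#' @param x A [run_chart()].
#' @param ... Unused.
#' @return A tibble with one row per point: `obs`, `value`, optional
#'   `label`, `position` (relative to the median), `baseline` (logical),
#'   and the chart `median`.
#' @method tidy run_chart
#' @export
tidy.run_chart <- function(x, ...) {
  dplyr::mutate(
    x$data,
    baseline = .data$obs <= x$baseline_len,
    median = x$median
  )
}

#' One-row summary of a run chart
#'
#' @param x A [run_chart()].
#' @param ... Unused.
#' @return The [run_stats()] tibble for the chart.
#' @method glance run_chart
#' @export
glance.run_chart <- function(x, ...) run_stats(x)
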