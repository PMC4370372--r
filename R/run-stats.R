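#' Run statistics of a chart
#'
#' Computes the median-based statistics that every run chart rule set
#' consumes. A *run* is a maximal block of consecutive points on the same
#' side of the median; points on the median are removed from the sequence
#' first (they neither extend nor break a run). A *crossing* is an adjacent
#' pair of useful points on opposite sides, so the number of runs is always
#' the number of crossings plus one. The *longest trend* is the largest
#' number of points moving strictly in one direction, with consecutive
#' repeated values collapsed to a single point; it is computed on the raw
#' series and ignores the median entirely.
#'
#' A series with no useful observations (every point on the median) returns
#' all run counts as zero rather than erroring, so rule engines can report
#' the chart as not evaluable.
#'
#' @param x A [run_chart()], a numeric vector, or a data frame (passed to
#'   [run_chart()] together with `...`).
#' @param ... For vectors and data frames, arguments forwarded to
#'   [run_chart()] (`value`, `baseline`, ...).
#'
#' @return A one-row tibble with columns `n_obs`, `baseline_len`, `median`,
#'   `n_useful`, `n_crossings`, `n_runs`, `longest_run`, `longest_trend`.
#'
#' @examples
#' set.seed(7)
#' run_stats(rnorm(24), baseline = 12)
#' @export
run_stats <- function(x, ...) {
  chart <- if (inherits(x, "run_chart")) x else run_chart(x, ...)
  signs <- as.integer(chart$data$position) - 2L   # below/on/above -> -1/0/1
  counts <- runs_from_signs(signs[signs != 0L])
  tibble::tibble(
    n_obs = nrow(chart$data),
    baseline_len = chart$baseline_len,
    median = chart$median,
    n_useful = counts[["n_useful"]],
    n_crossings = counts[["n_crossings"]],
    n_runs = counts[["n_runs"]],
    longest_run = counts[["longest_run"]],
    longest_trend = longest_trend(chart$data$value)
  )
}

# Runs/crossings counts for a +/-1 sign sequence with on-median points
# already removed.
runs_from_signs <- function(signs) {
  n <- length(signs)
  if (n == 0L) {
    return(c(n_useful = 0L, n_crossings = 0L, n_runs = 0L, longest_run = 0L))
  }
  r <- rle(signs)
  c(
    n_useful = n,
    n_crossings = length(r$lengths) - 1L,
    n_runs = length(r$lengths),
    longest_run = max(r$lengths)
  )
}

#' Longest trend in a series
#'
#' The number of points in the longest strictly monotone stretch of the
#' series, after collapsing consecutive equal values to a single point.
#' Repeats therefore neither extend nor break a trend. A direction change
#' starts a new stretch at the pivot, which belongs to both the ascending
#' and the descending stretch. The median plays no role.
#'
#' @param values Numeric series; an empty series yields 0 and a single
#'   point yields 1.
#' @return A non-negative integer.
#' @examples
#' longest_trend(c(1, 2, 3, 3, 4))     # 4: collapses to 1,2,3,4
#' longest_trend(c(5, 4, 3, 2, 1, 2))  # 5: the descending stretch
#' @export
longest_trend <- function(values) {
  v <- round(as.double(values), .rc_digits)
  v <- v[!duplicated_run(v)]
  n <- length(v)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  max(rle(sign(diff(v)))$lengths) + 1L
}

# TRUE where a value repeats its immediate predecessor.
duplicated_run <- function(v) {
  if (length(v) == 0) return(logical(0))
  c(FALSE, diff(v) == 0)
}
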