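#' Dynamic signal limits of the Anhoej rules
#'
#' The Anhoej rules flag non-random variation when the longest run is
#' *longer* than an upper prediction limit or the curve crosses the median
#' *fewer* times than a lower prediction limit, both limits depending only
#' on the number of useful observations `n`:
#'
#' * longest-run UPL: `round(log2(n) + 3)`, rounding halves up;
#' * crossings LPL: the smallest `k` with `pbinom(k, n - 1, 0.5) >= 0.05`,
#'   i.e. the 5% quantile of the number of crossings expected from a random
#'   process, in which each of the `n - 1` adjacent pairs crosses the
#'   median independently with probability one half.
#'
#' @param n_useful Number of useful observations (points not on the
#'   median). Vectorised; zeros give `NA` limits (the chart is not
#'   evaluable).
#' @return A tibble with columns `n_useful`, `longest_run_upl`,
#'   `crossings_lpl`.
#' @examples
#' anhoej_limits(24)  # UPL 8, LPL 8
#' anhoej_limits(10:14)
#' @export
anhoej_limits <- function(n_useful) {
  n <- vet_n_useful(n_useful)
  ok <- n >= 1L
  upl <- cross <- rep(NA_integer_, length(n))
  upl[ok] <- as.integer(floor(log2(n[ok]) + 3 + 0.5))  # round half up
  cross[ok] <- as.integer(qbinom(0.05, n[ok] - 1L, 0.5))
  tibble::tibble(
    n_useful = n,
    longest_run_upl = upl,
    crossings_lpl = cross
  )
}

#' Two-sided band for the expected number of runs
#'
#' The Perla and Carey rule sets test whether the observed number of runs
#' falls outside a two-sided band. The band is derived from the binomial
#' crossings model: the 2.5% and 97.5% quantiles of
#' `Binomial(n_useful - 1, 0.5)` crossings, converted to runs via
#' runs = crossings + 1. Run counts inside the band (inclusive) do not
#' signal.
#'
#' @param n_useful Number of useful observations; vectorised, zeros give
#'   `NA`.
#' @return A tibble with columns `n_useful`, `runs_lpl`, `runs_upl`.
#' @examples
#' runs_band(24)  # 8 to 17 runs
#' @export
runs_band <- function(n_useful) {
  n <- vet_n_useful(n_useful)
  ok <- n >= 1L
  lo <- hi <- rep(NA_integer_, length(n))
  lo[ok] <- as.integer(qbinom(0.025, n[ok] - 1L, 0.5)) + 1L
  hi[ok] <- as.integer(qbinom(0.975, n[ok] - 1L, 0.5)) + 1L
  tibble::tibble(n_useful = n, runs_lpl = lo, runs_upl = hi)
}

#' All signal limits for a given number of useful observations
#'
#' Convenience wrapper joining [anhoej_limits()] and [runs_band()].
#'
#' @inheritParams anhoej_limits
#' @return A tibble with columns `n_useful`, `longest_run_upl`,
#'   `crossings_lpl`, `runs_lpl`, `runs_upl`.
#' @export
signal_limits <- function(n_useful) {
  dplyr::left_join(anhoej_limits(n_useful), runs_band(n_useful),
                   by = "n_useful")
}

vet_n_useful <- function(n_useful) {
  if (length(n_useful) == 0 || !is.numeric(n_useful) || anyNA(n_useful) ||
      any(n_useful < 0) || any(n_useful != trunc(n_useful))) {
    abort("`n_useful` must be non-negative whole numbers.")
  }
  as.integer(n_useful)
}

rule_set_names <- c("anhoej", "perla", "carey")

#' Apply run chart rule sets to run statistics
#'
#' Evaluates one or more published rule sets on the statistics of one or
#' more run charts and reports the outcome of every component test plus the
#' overall signal (any component positive). The three sets are:
#'
#' * **Anhoej**: longest run above the dynamic UPL, or crossings below the
#'   dynamic LPL (see [anhoej_limits()]); both comparisons strict, so a
#'   chart sitting exactly on a limit does not signal.
#' * **Perla**: longest run of 6 or more; number of runs outside the
#'   [runs_band()]; trend of 5 or more points.
#' * **Carey**: longest run of *more than* 7 points (more than 8 when the
#'   chart has 20 or more useful observations); number of runs outside the
#'   [runs_band()]; trend of *more than* 6 points. The shift and trend
#'   comparisons are exclusive: a chart whose longest trend is exactly 6
#'   shows only random variation under Carey (see the package vignette for
#'   why the thresholds are read this way).
#'
#' A chart with no useful observations is not evaluable: every test and the
#' overall signal report `FALSE` and `evaluable` is `FALSE`.
#'
#' @param stats A tibble from [run_stats()] (any number of rows, one per
#'   chart), or a [run_chart()].
#' @param rules Character vector of rule sets, a subset of
#'   `c("anhoej", "perla", "carey")`, or `"all"` (default).
#' @return A tibble with one row per chart/rule-set combination: `chart`
#'   (row index into `stats`), `rule_set`, `n_useful`, `shift_test`,
#'   `crossings_test`, `runs_count_test`, `trend_test`, `signal`,
#'   `evaluable`. Component tests a rule set does not define are `FALSE`
#'   (Anhoej has no runs-count or trend test; Perla and Carey have no
#'   crossings test).
#' @examples
#' set.seed(4)
#' run_chart(rnorm(24), baseline = 12) |>
#'   run_stats() |>
#'   evaluate_rules()
#' @export
evaluate_rules <- function(stats, rules = "all") {
  if (inherits(stats, "run_chart")) stats <- run_stats(stats)
  needed <- c("n_useful", "n_crossings", "n_runs", "longest_run",
              "longest_trend")
  if (!is.data.frame(stats) || !all(needed %in% names(stats))) {
    abort("`stats` must be a run_chart or a tibble from run_stats().")
  }
  rules <- tolower(rules)
  if (identical(rules, "all")) rules <- rule_set_names
  bad <- setdiff(rules, rule_set_names)
  if (length(bad) > 0) {
    abort(sprintf("unknown rule set(s): %s", paste(bad, collapse = ", ")))
  }
  chart_id <- seq_len(nrow(stats))
  out <- purrr::map(rules, function(rs) {
    v <- switch(rs,
      anhoej = verdict_anhoej(stats),
      perla  = verdict_runs_trend(stats, shift_fires = stats$longest_run >= 6,
                                  trend_min = 5, trend_strict = FALSE),
      carey  = verdict_runs_trend(
        stats,
        shift_fires = stats$longest_run > ifelse(stats$n_useful >= 20, 8, 7),
        trend_min = 6, trend_strict = TRUE
      )
    )
    dplyr::bind_cols(tibble::tibble(chart = chart_id, rule_set = rs), v)
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$chart, match(.data$rule_set, rule_set_names))
}

verdict_anhoej <- function(stats) {
  ev <- stats$n_useful >= 1L
  lim <- anhoej_limits(stats$n_useful)
  shift <- ev & stats$longest_run > lim$longest_run_upl
  cross <- ev & stats$n_crossings < lim$crossings_lpl
  tibble::tibble(
    n_useful = stats$n_useful,
    shift_test = shift,
    crossings_test = cross,
    runs_count_test = FALSE,
    trend_test = FALSE,
    signal = shift | cross,
    evaluable = ev
  )
}

verdict_runs_trend <- function(stats, shift_fires, trend_min, trend_strict) {
  ev <- stats$n_useful >= 1L
  band <- runs_band(stats$n_useful)
  shift <- ev & shift_fires
  runs_out <- ev &
    (stats$n_runs < band$runs_lpl | stats$n_runs > band$runs_upl)
  trend <- if (trend_strict) stats$longest_trend > trend_min
           else stats$longest_trend >= trend_min
  trend <- ev & trend
  tibble::tibble(
    n_useful = stats$n_useful,
    shift_test = shift,
    crossings_test = FALSE,
    runs_count_test = runs_out,
    trend_test = trend,
    signal = shift | runs_out | trend,
    evaluable = ev
  )
}
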