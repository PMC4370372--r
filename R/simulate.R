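#' Define a grid of simulation conditions
#'
#' The reference design crosses baseline lengths 6, 12 and 18 with
#' post-baseline lengths 6, 12 and 18 (nine conditions). In the shifted arm
#' of each condition the process mean moves up by `shift_sd` standard
#' deviations for every post-baseline point; the unshifted arm has no
#' change. With the default 1000 replicates per arm the full grid comprises
#' 18,000 simulated run charts.
#'
#' @param baseline_len,post_len Integer vectors of baseline and
#'   post-baseline lengths; the grid is their full crossing.
#' @param shift_sd Size of the sustained shift, in standard deviations of
#'   the point-to-point variation (default 2).
#' @param distribution `"normal"` (standard normal; without loss of
#'   generality since all rules are location/scale invariant) or
#'   `"poisson"` (counts with mean `lambda`; a shift adds
#'   `shift_sd * sqrt(lambda)` to the post-baseline mean).
#' @param lambda Poisson mean (default 16, keeping skewness mild and the
#'   2 SD shifted mean at the integer 24).
#' @param n_reps Replicates per arm and condition (default 1000).
#' @return A tibble with one row per condition and columns `condition`,
#'   `baseline_len`, `post_len`, `shift_sd`, `distribution`, `lambda`,
#'   `n_reps`.
#' @examples
#' sim_conditions()
#' sim_conditions(baseline_len = 12, post_len = 12, n_reps = 200)
#' @export
sim_conditions <- function(baseline_len = c(6L, 12L, 18L),
                           post_len = c(6L, 12L, 18L),
                           shift_sd = 2,
                           distribution = c("normal", "poisson"),
                           lambda = 16,
                           n_reps = 1000L) {
  distribution <- match.arg(distribution)
  if (any(baseline_len < 1) || any(post_len < 1)) {
    abort("baseline and post-baseline lengths must be positive.")
  }
  if (shift_sd < 0) abort("`shift_sd` must be non-negative.")
  if (n_reps < 1) abort("`n_reps` must be a positive integer.")
  if (distribution == "poisson" && lambda <= 0) {
    abort("`lambda` must be positive.")
  }
  grid <- tidyr::expand_grid(
    baseline_len = as.integer(baseline_len),
    post_len = as.integer(post_len)
  )
  tibble::tibble(
    condition = paste0(grid$baseline_len, ":", grid$post_len),
    grid,
    shift_sd = shift_sd,
    distribution = distribution,
    lambda = lambda,
    n_reps = as.integer(n_reps)
  )
}

# Draw a baseline_len + post_len series from the condition's distribution,
# with the shift applied to the post-baseline segment when asked for.
# Uses (and advances) the current RNG state.
draw_series <- function(baseline_len, post_len, shifted, shift_sd,
                        distribution, lambda) {
  n <- baseline_len + post_len
  if (distribution == "normal") {
    y <- rnorm(n)
    if (shifted) y[(baseline_len + 1):n] <- y[(baseline_len + 1):n] + shift_sd
  } else {
    mu_post <- if (shifted) lambda + shift_sd * sqrt(lambda) else lambda
    y <- c(rpois(baseline_len, lambda), rpois(post_len, mu_post))
  }
  y
}

#' Simulate a single run chart with known truth
#'
#' Draws one series under a simulation condition and wraps it as a
#' [run_chart()] whose median comes from the baseline segment only. The
#' truth (shift present or not) is attached as attribute `shifted`.
#'
#' @param baseline_len,post_len Segment lengths.
#' @param shifted Introduce the shift in the post-baseline segment?
#' @param shift_sd,distribution,lambda See [sim_conditions()].
#' @return A [run_chart()] with attribute `shifted`.
#' @examples
#' set.seed(1)
#' simulate_run_chart(12, 12, shifted = TRUE)
#' @export
simulate_run_chart <- function(baseline_len, post_len, shifted = FALSE,
                               shift_sd = 2,
                               distribution = c("normal", "poisson"),
                               lambda = 16) {
  distribution <- match.arg(distribution)
  y <- draw_series(baseline_len, post_len, shifted, shift_sd,
                   distribution, lambda)
  chart <- run_chart(y, baseline = baseline_len)
  attr(chart, "shifted") <- shifted
  chart
}

#' Simulate run statistics in bulk
#'
#' Fast path used by [run_simulation_grid()]: draws `n` independent series
#' under one condition/arm and returns their [run_stats()] rows without
#' materialising chart objects. Exposed so calibration studies (e.g.
#' false-signal rates of individual tests) can work at the per-chart level.
#'
#' @inheritParams simulate_run_chart
#' @param n Number of charts.
#' @return A tibble of `n` [run_stats()] rows plus a `shifted` column.
#' @examples
#' set.seed(2)
#' st <- simulate_run_stats(100, 12, 12)
#' mean(evaluate_rules(st, "anhoej")$signal)  # false-signal rate
#' @export
simulate_run_stats <- function(n, baseline_len, post_len, shifted = FALSE,
                               shift_sd = 2,
                               distribution = c("normal", "poisson"),
                               lambda = 16) {
  distribution <- match.arg(distribution)
  len <- baseline_len + post_len
  base_idx <- seq_len(baseline_len)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    y <- draw_series(baseline_len, post_len, shifted, shift_sd,
                     distribution, lambda)
    med <- median(y[base_idx])
    s <- classify_values(y, med)
    s <- as.integer(s) - 2L
    counts <- runs_from_signs(s[s != 0L])
    rows[[i]] <- c(counts, longest_trend = longest_trend(y), median = med)
  }
  m <- do.call(rbind, rows)
  tibble::tibble(
    n_obs = len,
    baseline_len = as.integer(baseline_len),
    median = m[, "median"],
    n_useful = as.integer(m[, "n_useful"]),
    n_crossings = as.integer(m[, "n_crossings"]),
    n_runs = as.integer(m[, "n_runs"]),
    longest_run = as.integer(m[, "longest_run"]),
    longest_trend = as.integer(m[, "longest_trend"]),
    shifted = shifted
  )
}

# Deterministic per-condition RNG substream: any subset of conditions
# reproduces the charts of the full grid. Keys and seeds stay below 2^31.
condition_seed <- function(root_seed, baseline_len, post_len, distribution) {
  key <- baseline_len * 1000 + post_len * 10 +
    (distribution == "poisson")
  as.integer((as.double(root_seed) * 7 + key * 104729) %% 2147483647)
}

#' Run the simulation study over a grid of conditions
#'
#' For every condition, simulates `n_reps` charts without and `n_reps`
#' charts with a post-baseline shift, applies every requested rule set to
#' every chart (a paired design: between-rule comparisons carry no
#' generation noise), accumulates the 2x2 truth-by-signal table, and
#' derives sensitivity, specificity and likelihood ratios via
#' [diagnose()]. Charts a rule set cannot evaluate (no useful
#' observations, possible only with integer-valued data) count as
#' no-signal and are tallied in `n_unevaluable`.
#'
#' @param conditions A tibble from [sim_conditions()].
#' @param rules Rule sets to score, as in [evaluate_rules()].
#' @param seed Optional integer root seed. Each condition derives its own
#'   substream from it, so rerunning any subset of conditions reproduces
#'   the same charts.
#' @return A tibble of class `rundx_sim` with one row per condition and
#'   rule set: the condition columns, `rule_set`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`, `n_unevaluable`.
#'   Attribute `n_charts` records the total number of simulated charts.
#' @examples
#' run_simulation_grid(sim_conditions(n_reps = 20), seed = 1)
#' @export
run_simulation_grid <- function(conditions = sim_conditions(),
                                rules = "all", seed = NULL) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0) {
    abort("`conditions` must be a non-empty tibble from sim_conditions().")
  }
  if (identical(rules, "all")) rules <- rule_set_names
  res <- purrr::pmap(conditions, function(condition, baseline_len, post_len,
                                          shift_sd, distribution, lambda,
                                          n_reps, ...) {
    if (!is.null(seed)) {
      set.seed(condition_seed(seed, baseline_len, post_len, distribution))
    }
    stats <- dplyr::bind_rows(
      simulate_run_stats(n_reps, baseline_len, post_len, shifted = FALSE,
                         shift_sd = shift_sd, distribution = distribution,
                         lambda = lambda),
      simulate_run_stats(n_reps, baseline_len, post_len, shifted = TRUE,
                         shift_sd = shift_sd, distribution = distribution,
                         lambda = lambda)
    )
    verdicts <- evaluate_rules(stats, rules)
    verdicts$shifted <- stats$shifted[verdicts$chart]
    cells <- verdicts |>
      dplyr::group_by(.data$rule_set) |>
      dplyr::summarise(
        tp = sum(.data$signal & .data$shifted),
        fp = sum(.data$signal & !.data$shifted),
        tn = sum(!.data$signal & !.data$shifted),
        fn = sum(!.data$signal & .data$shifted),
        n_unevaluable = sum(!.data$evaluable),
        .groups = "drop"
      ) |>
      dplyr::arrange(match(.data$rule_set, rule_set_names))
    dplyr::bind_cols(
      tibble::tibble(
        condition = condition, baseline_len = baseline_len,
        post_len = post_len, shift_sd = shift_sd,
        distribution = distribution, lambda = lambda, n_reps = n_reps
      ),
      diagnose(cells$tp, cells$fp, cells$tn, cells$fn)
    ) |>
      dplyr::mutate(rule_set = cells$rule_set,
                    n_unevaluable = cells$n_unevaluable,
                    .after = "n_reps")
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_charts") <- sum(conditions$n_reps) * 2L
  attr(out, "seed") <- seed
  class(out) <- c("rundx_sim", class(out))
  out
}

#' @export
print.rundx_sim <- function(x, ...) {
  cat(sprintf("<rundx_sim> %d simulated run charts, %d condition(s)\n",
              attr(x, "n_charts"), length(unique(x$condition))))
  NextMethod()
}

#' Summary of a simulation study
#'
#' @param x A `rundx_sim` result from [run_simulation_grid()].
#' @param ... Unused.
#' @return A one-row tibble: number of charts, conditions, replicates per
#'   arm, rule sets scored, and the root seed (`NA` if none was given).
#' @method glance rundx_sim
#' @export
glance.rundx_sim <- function(x, ...) {
  tibble::tibble(
    n_charts = attr(x, "n_charts"),
    n_conditions = length(unique(x$condition)),
    n_reps = unique(x$n_reps)[1],
    rule_sets = paste(unique(x$rule_set), collapse = ","),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Write simulation results to CSV files
#'
#' Writes `contingency.csv` (condition, rule set and the 2x2 counts) and
#' `diagnostics.csv` (the full result table including sensitivity,
#' specificity and likelihood ratios) into a directory.
#'
#' @param sim A `rundx_sim` from [run_simulation_grid()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the paths of the two files.
#' @export
write_simulation_results <- function(sim, dir) {
  stopifnot(inherits(sim, "rundx_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    contingency = file.path(dir, "contingency.csv"),
    diagnostics = file.path(dir, "diagnostics.csv")
  )
  sim |>
    dplyr::select("condition", "rule_set", "tp", "fp", "tn", "fn") |>
    readr::write_csv(paths[["contingency"]])
  readr::write_csv(tibble::as_tibble(sim), paths[["diagnostics"]])
  invisible(paths)
}
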