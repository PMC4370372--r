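# Shorthand for a hand-built statistics row.
stats_row <- function(n_useful, longest_run, n_crossings,
                      longest_trend = 1L, n_runs = n_crossings + 1L) {
  tibble::tibble(
    n_obs = n_useful, baseline_len = n_useful, median = 0,
    n_useful = n_useful, n_crossings = n_crossings, n_runs = n_runs,
    longest_run = longest_run, longest_trend = longest_trend
  )
}

one_verdict <- function(stats, rule) {
  v <- evaluate_rules(stats, rule)
  expect_equal(nrow(v), nrow(stats))
  v
}

test_that("Anhoej limits match the published anchors and a brute CDF sum", {
  lim <- anhoej_limits(24)
  expect_equal(lim$longest_run_upl, 8L)
  expect_equal(lim$crossings_lpl, 8L)
  lim27 <- anhoej_limits(27)
  expect_equal(lim27$longest_run_upl, 8L)
  expect_equal(lim27$crossings_lpl, 9L)

  # crossings LPL = smallest k whose binomial CDF reaches 5%, summed by hand
  for (n in 10:100) {
    cdf <- cumsum(choose(n - 1, 0:(n - 1)) / 2^(n - 1))
    expect_equal(anhoej_limits(n)$crossings_lpl,
                 as.integer(min(which(cdf >= 0.05)) - 1L))
  }

  # limits never decrease with more useful observations
  lims <- anhoej_limits(1:200)
  expect_true(all(diff(lims$longest_run_upl) >= 0))
  expect_true(all(diff(lims$crossings_lpl) >= 0))

  expect_true(is.na(anhoej_limits(0)$longest_run_upl))
  expect_error(anhoej_limits(-1), "non-negative")
})

test_that("runs band matches a brute binomial-quantile summation", {
  b2 <- runs_band(2)
  expect_equal(c(b2$runs_lpl, b2$runs_upl), c(1L, 2L))  # never signals

  for (n in c(5, 10, 24, 27, 50)) {
    cdf <- cumsum(choose(n - 1, 0:(n - 1)) / 2^(n - 1))
    lo <- min(which(cdf >= 0.025)) - 1L
    hi <- min(which(cdf >= 0.975)) - 1L
    b <- runs_band(n)
    expect_equal(b$runs_lpl, as.integer(lo + 1L))
    expect_equal(b$runs_upl, as.integer(hi + 1L))
  }
})

test_that("Anhoej verdicts reproduce the 24-point reference charts", {
  # shifted chart: longest run 13, 6 crossings -> both tests fire
  v <- one_verdict(stats_row(24, longest_run = 13, n_crossings = 6), "anhoej")
  expect_true(v$shift_test && v$crossings_test && v$signal)

  # random chart: longest run 3, 13 crossings -> nothing fires
  v <- one_verdict(stats_row(24, longest_run = 3, n_crossings = 13), "anhoej")
  expect_false(v$signal)

  # limits are non-signalling boundaries: strict inequalities
  v <- one_verdict(stats_row(24, longest_run = 8, n_crossings = 8), "anhoej")
  expect_false(v$signal)

  # Anhoej defines no runs-count or trend test
  expect_false(v$runs_count_test)
  expect_false(v$trend_test)
})

test_that("Carey thresholds are exclusive and chart-size dependent", {
  # 20+ useful observations: a run of 8 sits on the limit and does not signal
  expect_false(one_verdict(stats_row(24, 7, 11), "carey")$shift_test)
  expect_false(one_verdict(stats_row(24, 8, 11), "carey")$shift_test)
  expect_true(one_verdict(stats_row(24, 9, 11), "carey")$shift_test)
  # below 20 useful observations the limit is a run of 7
  expect_false(one_verdict(stats_row(18, 7, 8), "carey")$shift_test)
  expect_true(one_verdict(stats_row(18, 8, 8), "carey")$shift_test)
  # a trend of exactly 6 is random variation; 7 signals
  expect_false(
    one_verdict(stats_row(24, 3, 11, longest_trend = 6), "carey")$trend_test
  )
  expect_true(
    one_verdict(stats_row(24, 3, 11, longest_trend = 7), "carey")$trend_test
  )
})

test_that("Perla thresholds are inclusive", {
  expect_true(one_verdict(stats_row(24, 6, 11), "perla")$shift_test)
  expect_false(one_verdict(stats_row(24, 5, 11), "perla")$shift_test)
  expect_true(
    one_verdict(stats_row(24, 3, 11, longest_trend = 5), "perla")$trend_test
  )
  expect_false(
    one_verdict(stats_row(24, 3, 11, longest_trend = 4), "perla")$signal
  )
})

test_that("the hospital-infection example chart signals only under Perla", {
  # 27 useful observations, longest run 6, 11 crossings, longest trend 6
  st <- stats_row(27, longest_run = 6, n_crossings = 11, longest_trend = 6)
  v <- evaluate_rules(st)
  v <- split(v, v$rule_set)
  expect_false(v$anhoej$signal)
  expect_false(v$carey$signal)
  expect_true(v$perla$signal)
  expect_true(v$perla$shift_test && v$perla$trend_test)
  expect_false(v$perla$runs_count_test)
})

test_that("charts with every point on the median are not evaluable", {
  st <- run_stats(run_chart(rep(3, 8)))
  v <- evaluate_rules(st)
  expect_true(all(!v$evaluable))
  expect_true(all(!v$signal))
  expect_true(all(!v$shift_test & !v$crossings_test &
                    !v$runs_count_test & !v$trend_test))
})

test_that("verdicts are pure functions of the statistics", {
  set.seed(42)
  st <- simulate_run_stats(20, 12, 12)
  expect_identical(evaluate_rules(st), evaluate_rules(st))
})

test_that("Perla is at least as sensitive as Anhoej under shifts", {
  set.seed(606)
  for (cond in list(c(6, 12), c(12, 12), c(12, 18))) {
    st <- simulate_run_stats(400, cond[1], cond[2], shifted = TRUE)
    v <- evaluate_rules(st, c("anhoej", "perla"))
    sens <- tapply(v$signal, v$rule_set, mean)
    expect_gte(sens[["perla"]], sens[["anhoej"]])
  }
})

test_that("the runs-count test alone is calibrated near its 5% level", {
  set.seed(707)
  st <- simulate_run_stats(10000, 12, 12, shifted = FALSE)
  rate <- mean(evaluate_rules(st, "perla")$runs_count_test)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
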