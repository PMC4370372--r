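# Independent brute-force oracles, deliberately written as plain scans so
# they share no code with the implementation they check.

# Walk a +/-1 sign sequence (zeros = on-median points are dropped first)
# counting runs, crossings and the longest run one step at a time.
brute_runs <- function(signs) {
  signs <- signs[signs != 0]
  n <- length(signs)
  if (n == 0) {
    return(list(n_useful = 0L, n_crossings = 0L, n_runs = 0L,
                longest_run = 0L))
  }
  n_runs <- 1L
  n_crossings <- 0L
  cur <- 1L
  longest <- 1L
  if (n > 1) {
    for (i in 2:n) {
      if (signs[i] == signs[i - 1]) {
        cur <- cur + 1L
      } else {
        n_crossings <- n_crossings + 1L
        n_runs <- n_runs + 1L
        cur <- 1L
      }
      if (cur > longest) longest <- cur
    }
  }
  list(n_useful = n, n_crossings = n_crossings, n_runs = n_runs,
       longest_run = longest)
}

# O(n^2) longest-trend scanner: collapse repeats, then test every
# sub-stretch for strict monotonicity.
brute_longest_trend <- function(values) {
  v <- values
  if (length(v) > 1) v <- v[c(TRUE, diff(v) != 0)]
  n <- length(v)
  if (n == 0) return(0L)
  best <- 1L
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- diff(v[i:j])
        if (all(d > 0) || all(d < 0)) best <- max(best, j - i + 1L)
      }
    }
  }
  as.integer(best)
}

# All sign sequences of length n as a (2^n x n) matrix of +/-1.
all_sign_sequences <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  dimnames(m) <- NULL
  m
}

# Chi-square goodness of fit of observed counts against Binomial(size, 1/2),
# pooling tail categories until every expected count is at least 5.
binomial_gof_pvalue <- function(observed_values, size) {
  probs <- stats::dbinom(0:size, size, 0.5)
  counts <- tabulate(observed_values + 1L, nbins = size + 1L)
  expected <- probs * length(observed_values)
  lo <- 1L
  while (sum(expected[seq_len(lo)]) < 5 && lo < size) lo <- lo + 1L
  hi <- size + 1L
  while (sum(expected[hi:(size + 1L)]) < 5 && hi > lo + 1L) hi <- hi - 1L
  pool <- function(x) c(sum(x[seq_len(lo)]), x[(lo + 1L):(hi - 1L)],
                        sum(x[hi:(size + 1L)]))
  suppressWarnings(
    stats::chisq.test(pool(counts), p = pool(probs) / sum(probs))$p.value
  )
}
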