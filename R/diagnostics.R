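#' Diagnostic measures from a 2x2 truth-by-signal table
#'
#' Treats a run chart rule set as a diagnostic test for non-random
#' variation and summarises its performance against known truth:
#'
#' * sensitivity = TP / (TP + FN), the true-positive rate;
#' * specificity = TN / (TN + FP), the true-negative rate;
#' * positive likelihood ratio LR+ = sensitivity / (1 - specificity);
#' * negative likelihood ratio LR- = (1 - sensitivity) / specificity.
#'
#' An LR+ above 10 (LR- below 0.1) is conventionally strong evidence for
#' (against) the condition tested. Division by zero is reported as is: a
#' perfect test has `lr_pos = Inf` and `lr_neg = 0`; no continuity
#' correction is applied. Counts are kept in the output so no precision is
#' lost downstream.
#'
#' @param tp,fp,tn,fn Non-negative integer counts of true/false
#'   positives/negatives; vectorised in parallel. Each element must come
#'   from at least one truly-positive chart (`tp + fn >= 1`) and one
#'   truly-negative chart (`tn + fp >= 1`).
#' @return A tibble with columns `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `lr_pos`, `lr_neg`.
#' @examples
#' diagnose(tp = 885, fp = 73, tn = 927, fn = 115)
#' @export
diagnose <- function(tp, fp, tn, fn) {
  counts <- vctrs_recycle(tp = tp, fp = fp, tn = tn, fn = fn)
  with(counts, {
    if (any(c(tp, fp, tn, fn) < 0) || anyNA(c(tp, fp, tn, fn))) {
      abort("counts must be non-negative and non-missing.")
    }
    if (any(tp + fn < 1) || any(tn + fp < 1)) {
      abort("each arm needs at least one chart: tp + fn >= 1 and tn + fp >= 1.")
    }
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    tibble::tibble(
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens,
      specificity = spec,
      lr_pos = sens / (1 - spec),
      lr_neg = (1 - sens) / spec
    )
  })
}

# Recycle scalar count arguments against the longest one.
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != n & lengths(args) != 1L
  if (any(bad)) abort("count arguments must have equal length or length 1.")
  lapply(args, rep_len, length.out = n)
}
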