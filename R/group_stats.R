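# Two-group comparisons and summary statistics with the display
# conventions used throughout the figures: box limits at the first and
# third quartiles, whiskers to the most extreme values within 1.5 IQR of
# the box ends, and Student t-tests classed "moderate" (0.01 < p < 0.05)
# or "strong" (p <= 0.01).

#' Boxplot summary of one sample
#'
#' Quartiles use linear interpolation of the empirical distribution
#' (`stats::quantile` type 7), fixed so whisker and outlier results are
#' reproducible bit-for-bit. Whiskers extend from each box end to the most
#' extreme data value within 1.5 times the interquartile range; values
#' beyond are listed as outliers.
#'
#' @param values Numeric sample (n >= 1).
#' @param label Optional group label.
#' @return List with `label, n, median, q1, q3, iqr, whisker_low,
#'   whisker_high, outliers`.
#' @export
boxplot_summary <- function(values, label = "") {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values))) {
    stop_conebend("sample must be non-empty and finite", "conebend_domain_error")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(label = label, n = length(values),
       median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

classify_significance <- function(p, p_moderate = 0.05, p_strong = 0.01) {
  if (p <= p_strong) "strong" else if (p < p_moderate) "moderate" else "ns"
}

#' Two-sample Student t-test with significance classes
#'
#' Classical pooled-variance two-sided test (Welch's unequal-variance form
#' available behind `welch = TRUE`). The p-value is classed `ns`
#' (p >= 0.05), `moderate` (0.01 < p < 0.05, the "dashed" convention) or
#' `strong` (p <= 0.01, "solid"). Degenerate zero-variance samples follow
#' the convention p = 1 for identical means and p = 0 otherwise.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param welch Use the Welch unequal-variance form instead of the pooled
#'   test.
#' @param p_moderate,p_strong Class thresholds.
#' @return A `comparison_result`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significance_class`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
students_t <- function(a, b, welch = FALSE,
                       p_moderate = 0.05, p_strong = 0.01) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop_conebend("each group needs n >= 2", "conebend_domain_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    res <- list(t_statistic = if (p == 1) 0 else Inf * sign(mean(a) - mean(b)),
                degrees_of_freedom = length(a) + length(b) - 2, p_value = p)
  } else {
    tt <- t.test(a, b, var.equal = !welch)
    res <- list(t_statistic = unname(tt$statistic),
                degrees_of_freedom = unname(tt$parameter),
                p_value = tt$p.value)
  }
  res$significance_class <- classify_significance(res$p_value, p_moderate, p_strong)
  res$mean_a <- mean(a); res$mean_b <- mean(b)
  res$n_a <- length(a); res$n_b <- length(b)
  structure(res, class = "comparison_result")
}
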