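# Statistical comparison of model metrics across cross-validation folds,
# and the instrument-noise floor of the total severity score.

new_ttest_result <- function(t_stat, p_value, df, alpha, degenerate = FALSE) {
  structure(list(t_stat = t_stat, p_value = p_value, df = df, alpha = alpha,
                 significant = is.finite(p_value) && p_value < alpha,
                 degenerate = degenerate),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t-stat = %.2f, p = %s, df = %d%s%s\n",
              x$t_stat, format_pvalue(x$p_value), x$df,
              if (x$significant) " (significant)" else "",
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Paired t-test on fold-level metrics
#'
#' Compares two models' per-fold metric values with a paired Student t-test
#' (df = n - 1, so df = 4 for the five-fold protocol), two-sided.
#'
#' @param metrics_a,metrics_b equal-length numeric vectors of fold metrics.
#' @param alpha significance level (default 0.05).
#' @return a `ttest_result`.
#' @export
ttest_from_folds <- function(metrics_a, metrics_b, alpha = 0.05) {
  if (length(metrics_a) != length(metrics_b))
    stop("argument error: fold vectors must have equal length")
  n <- length(metrics_a)
  if (n < 2) stop("argument error: need at least two folds")
  d <- metrics_a - metrics_b
  if (stats::sd(d) == 0) {
    # zero variance of differences: t is 0 or unbounded
    if (mean(d) == 0) return(new_ttest_result(0, 1, n - 1L, alpha,
                                              degenerate = TRUE))
    return(new_ttest_result(sign(mean(d)) * Inf, 0, n - 1L, alpha,
                            degenerate = TRUE))
  }
  ht <- stats::t.test(metrics_a, metrics_b, paired = TRUE)
  new_ttest_result(unname(ht$statistic), ht$p.value,
                   as.integer(unname(ht$parameter)), alpha)
}

#' t-test from fold-aggregate summaries (mean ± standard error)
#'
#' Reconstructs the comparison t-statistic from printed mean/SE summaries:
#' `t = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)`, two-sided p at the given
#' degrees of freedom.  This reproduces published comparison tables when
#' only summary rows are available.
#'
#' @param mean_a,se_a,mean_b,se_b fold-aggregate mean and standard error of
#'   the two models' metric.
#' @param df degrees of freedom (4 for five folds).
#' @param alpha significance level.
#' @return a `ttest_result`.
#' @export
ttest_from_summary <- function(mean_a, se_a, mean_b, se_b, df, alpha = 0.05) {
  if (se_a < 0 || se_b < 0)
    stop("argument error: standard errors must be non-negative")
  if (se_a == 0 && se_b == 0)
    stop("degenerate-input error: both standard errors are zero")
  t_stat <- (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  new_ttest_result(t_stat, p, as.integer(df), alpha)
}

#' Instrument-noise floor of the total severity score
#'
#' Aggregates published per-part error variances of the instrument into a
#' total noise component by summing the per-part standard deviations
#' (`sum(sqrt(v))`).  A model whose RMSE falls below this floor predicts the
#' score more precisely than the instrument measures it.
#'
#' @param part_error_variances non-negative per-part error variances.
#' @return the noise floor, in score points.
#' @export
noise_floor <- function(part_error_variances) {
  if (any(!is.finite(part_error_variances)) || any(part_error_variances < 0))
    stop("range error: error variances must be non-negative")
  sum(sqrt(part_error_variances))
}

#' Display-format a p-value
#'
#' Four decimals, with values below 5e-5 rendered as "0.000" (matching the
#' usual table display of vanishing p-values).
#'
#' @param p p-value in `[0, 1]`.
#' @return character scalar.
#' @export
format_pvalue <- function(p) {
  if (!is.finite(p)) return("NA")
  if (p < 5e-5) "0.000" else sprintf("%.4f", p)
}
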