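#' Two-tailed independent-samples t-test (pooled variance)
#'
#' Computes the pooled-variance two-sample t statistic, degrees of freedom
#' `n1 + n2 - 2`, two-tailed p value, and the central-t confidence interval
#' for the mean difference, either from summary statistics (group means,
#' SDs, sizes) or from raw samples (pass numeric vectors as the first two
#' arguments).
#'
#' @param mean1 mean of group 1, or a raw sample vector.
#' @param sd1 SD of group 1 (ignored when `mean1` is a sample).
#' @param n1 size of group 1 (ignored when `mean1` is a sample).
#' @param mean2 mean of group 2, or a raw sample vector.
#' @param sd2,n2 as for group 1.
#' @param conf_level confidence level of the interval.
#' @return list of class `ttest_result`: `t`, `df`, `p`, `ci95`,
#'   `mean_diff`, `se`.
#' @export
ttest_ind <- function(mean1, sd1 = NULL, n1 = NULL, mean2 = NULL,
                      sd2 = NULL, n2 = NULL, conf_level = 0.95) {
  if (length(mean1) > 1) { # raw samples
    x <- mean1
    y <- if (length(sd1) > 1) sd1 else mean2
    stopifnot(length(y) > 1)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
    sd1 <- stats::sd(x); n1 <- length(x); mean1 <- mean(x)
  }
  if (n1 < 2 || n2 < 2) stop("need at least two observations per group")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean1 - mean2
  t <- diff / se
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
         ci95 = c(diff - q * se, diff + q * se),
         mean_diff = diff, se = se),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.2f, p = %.3f, diff = %.3f, 95%% CI [%.2f, %.2f]\n",
              x$df, x$t, x$p, x$mean_diff, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`; monotone and order preserving.
#'
#' @param pvals raw p values.
#' @param m number of comparisons in the family (default `length(pvals)`).
#' @return adjusted p values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(m >= 1, all(pvals >= 0 & pvals <= 1))
  pmin(1, m * pvals)
}
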