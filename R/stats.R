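# Associational and comparison statistics used by the condition-level
# summaries: Spearman rank correlation (robust to the outlying initial
# cycles), one-sample and paired Student t-tests, and the Fisher transform
# for averaging correlation coefficients. Significance is two-tailed at
# 0.05 throughout. Repeated-measures ANOVA machinery is deliberately out
# of scope: the pipeline emits tidy long-format tables so any statistics
# package can run it.

#' Spearman rank correlation
#'
#' Spearman's rho on average ranks, with a two-tailed p-value from the
#' t-approximation on `n - 2` degrees of freedom (via
#' `stats::cor.test(..., method = "spearman", exact = FALSE)`).
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @return A tibble of class `regression_result` with `rho`, `p`, `n`, and
#'   `undefined` (`TRUE` when either input is constant).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) {
    stop("need at least 4 paired observations", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x),
                  undefined = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         undefined = FALSE)
}

#' One-sample Student t-test
#'
#' Tests whether the mean of `values` differs from `mu0`, two-tailed. Used
#' to compare the mean adaptation index of a condition to zero. A
#' zero-variance sample is flagged: the statistic is infinite (sign of the
#' mean difference) or `NaN` when the difference is also zero.
#'
#' @param values Numeric sample (n >= 2, finite).
#' @param mu0 Reference value.
#' @return List of class `test_result`: `statistic`, `df`, `p`, `estimate`
#'   (sample mean), `flagged`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L || !all(is.finite(values))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  df <- length(values) - 1L
  if (sd(values) == 0) {
    d <- mean(values) - mu0
    stat <- if (d == 0) NaN else sign(d) * Inf
    return(structure(list(statistic = stat, df = df,
                          p = if (d == 0) NA_real_ else 0,
                          estimate = mean(values), flagged = TRUE),
                     class = "test_result"))
  }
  tt <- t.test(values, mu = mu0)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, estimate = unname(tt$estimate),
                 flagged = FALSE),
            class = "test_result")
}

#' Paired Student t-test
#'
#' One-sample t-test of the pairwise differences `a - b` against zero;
#' used to compare steady-state AP positions to the initial ones.
#'
#' @param a,b Paired numeric samples of equal length.
#' @return A `test_result` as in [one_sample_t()]; `estimate` is the mean
#'   difference.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  one_sample_t(a - b, mu0 = 0)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %g, p = %.4g (estimate %.4g)%s\n",
              x$statistic, x$df, x$p, x$estimate,
              if (x$flagged) "  [zero variance]" else ""))
  invisible(x)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)`, with `r` clipped to +/-(1 - 1e-12) so coefficients of
#' exactly +/-1 transform to large finite values. Group-level correlation
#' summaries average z values and back-transform with [fisher_z_inv()].
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]", call. = FALSE)
  }
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' @rdname fisher_z
#' @param z Fisher-transformed value(s).
#' @export
fisher_z_inv <- function(z) {
  tanh(z)
}
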