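# Exponential adaptation model. Per-cycle series y_n (peak-to-peak
# displacement, or the cross-correlation coefficient) are fitted with
#   y = A + B * exp(-C * t),  t = n - 1,
# by damped (Levenberg-Marquardt) least squares with a multi-start grid.
# Fitting with the first cycle at t = 0 makes the intercept at cycle 1
# exactly I = A + B, which is the identity the derived indices rely on.
# Derived quantities: time constant tau = 1/|C| (in cycles; divided by the
# platform frequency for seconds) and the adaptation index
# AI = (A - I)/(A + I), negative when the series decays.

#' Fit the three-parameter exponential adaptation model
#'
#' Least-squares estimation of `(A, B, C)` in `y = A + B * exp(-C * t)`
#' with `t = n - 1`, minimizing the residual sum of squares by
#' Levenberg-Marquardt iterations started from a grid of 8 initial values
#' (`C0` in 1, 1/2, 1/4, 1/8 crossed with both signs of `B0`;
#' `A0` = mean of the last 5 points, `B0 = y[1] - A0`). The rate is bounded
#' so that `tau = 1/C` stays within `tau_bounds`; a fit on a bound, or with
#' `|B| < tol_B * |A|`, is flagged `degenerate` (indistinguishable from a
#' constant at the data's resolution, so its time constant is unreliable).
#' A zero-variance series falls back to the constant model `A = mean(y)`
#' with the degenerate flag set.
#'
#' @param y Per-cycle values (at least 5, all finite), or a `cycle_series`
#'   (its `pp` column is used).
#' @param n Cycle indices (1-based).
#' @param tau_bounds Allowed time-constant range in cycles.
#' @param tol_B Degeneracy threshold: fits with `|B| < tol_B * |A|` are
#'   flagged.
#' @return An object of class `exp_fit`: list with `A`, `B`, `C`, `rss`,
#'   `fitted`, `y`, `cycles`, `converged`, `degenerate`.
#' @export
fit_exponential <- function(y, n = NULL, tau_bounds = NULL, tol_B = 0.02) {
  if (inherits(y, "cycle_series")) {
    if (is.null(n)) n <- y$cycle
    y <- y$pp
  }
  y <- as.numeric(y)
  if (is.null(n)) n <- seq_along(y)
  stopifnot(length(n) == length(y))
  if (length(y) < 5L) {
    stop("need at least 5 cycles to fit the exponential model", call. = FALSE)
  }
  if (!all(is.finite(y))) {
    stop("non-finite values in the per-cycle series", call. = FALSE)
  }
  if (is.null(tau_bounds)) tau_bounds <- c(0.2, 3 * length(y))
  t <- n - 1

  constant_fit <- function() {
    A <- mean(y)
    structure(list(A = A, B = 0, C = NA_real_,
                   rss = sum((y - A)^2), fitted = rep(A, length(y)),
                   y = y, cycles = n, converged = TRUE, degenerate = TRUE),
              class = "exp_fit")
  }
  if (sd(y) == 0) return(constant_fit())

  C_lo <- 1 / max(tau_bounds)
  C_hi <- 1 / min(tau_bounds)
  A0 <- mean(tail(y, 5L))
  B0 <- y[1] - A0
  if (abs(B0) < 1e-12) B0 <- sd(y)
  starts <- expand.grid(B = c(B0, -B0), C = c(1, 1 / 2, 1 / 4, 1 / 8))
  starts$C <- pmin(pmax(starts$C, C_lo), C_hi)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A + B * exp(-C * t),
        data = list(y = y, t = t),
        start = list(A = A0, B = starts$B[i], C = starts$C[i]),
        lower = c(A = -Inf, B = -Inf, C = C_lo),
        upper = c(A = Inf, B = Inf, C = C_hi),
        control = minpack.lm::nls.lm.control(
          maxiter = 1024, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15 * (1 + best$rss)) {
      p <- coef(fit)
      best <- list(A = unname(p["A"]), B = unname(p["B"]),
                   C = unname(p["C"]), rss = rss,
                   fitted = as.numeric(fitted(fit)))
    }
  }
  if (is.null(best)) {
    return(constant_fit())
  }
  at_bound <- best$C <= C_lo * (1 + 1e-6) || best$C >= C_hi * (1 - 1e-6)
  small_B <- abs(best$B) < tol_B * max(abs(best$A), .Machine$double.eps)
  structure(
    c(best, list(y = y, cycles = n, converged = TRUE,
                 degenerate = at_bound || small_B)),
    class = "exp_fit"
  )
}

#' Derive time constant, intercept and adaptation index from a fit
#'
#' Completes an [fit_exponential()] result with the quantities the
#' analysis reports: `tau_cycles = 1/|C|` (time constants are positive by
#' definition; the direction of adaptation is carried by the sign of the
#' adaptation index), `tau_seconds = tau_cycles * cycle_duration`
#' (5.6 s per cycle at 0.18 Hz, 1.8 s at 0.56 Hz), the intercept at the
#' first cycle `I = A + B`, and the adaptation index
#' `AI = (A - I)/(A + I)`, negative when the series shrinks over the trial
#' (about -0.3 when the asymptote is half the intercept) and near zero for
#' negligible adaptation.
#'
#' @param fit An `exp_fit`.
#' @param frequency Platform translation frequency in Hz, for the
#'   cycles-to-seconds conversion; `NULL` leaves `tau_seconds` `NA`.
#' @return The `exp_fit` with fields `tau_cycles`, `tau_seconds`, `I`,
#'   `AI` added.
#' @export
derive_indices <- function(fit, frequency = NULL) {
  stopifnot(inherits(fit, "exp_fit"))
  fit$tau_cycles <- if (is.na(fit$C) || fit$C == 0) NA_real_ else 1 / abs(fit$C)
  fit$tau_seconds <- if (!is.null(frequency) && !is.na(fit$tau_cycles)) {
    fit$tau_cycles * cycle_duration(frequency)
  } else {
    NA_real_
  }
  fit$I <- fit$A + fit$B
  if (fit$A + fit$I <= 0) {
    stop("adaptation index undefined: A + I <= 0 (series not positive)",
         call. = FALSE)
  }
  fit$AI <- ai_of(fit$A, fit$I)
  fit
}

#' Goodness of fit of the exponential model
#'
#' Pearson correlation `R` between the observed and fitted per-cycle
#' values, with a two-tailed p-value from the t-distribution on `n - 2`
#' degrees of freedom. Note that because the curve was itself fitted to the
#' series, this p-value is optimistic under the null of no structure; it is
#' reported descriptively, and fits are never discarded on its account.
#'
#' @param y Observed per-cycle values; defaults to the series stored in the
#'   fit.
#' @param fit An `exp_fit`.
#' @return List with `R`, `p`, `df`, and `undefined` (`TRUE` when either
#'   series has zero variance, in which case `R` is `NA`).
#' @export
goodness_of_fit <- function(fit, y = fit$y) {
  stopifnot(inherits(fit, "exp_fit"), length(y) == length(fit$fitted))
  df <- length(y) - 2L
  if (sd(y) == 0 || sd(fit$fitted) == 0) {
    return(list(R = NA_real_, p = NA_real_, df = df, undefined = TRUE))
  }
  R <- cor(y, fit$fitted)
  tstat <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  list(R = R, p = 2 * pt(-abs(tstat), df), df = df, undefined = FALSE)
}

#' Fit, derive and assess in one call
#'
#' Runs [fit_exponential()], [derive_indices()] and [goodness_of_fit()] and
#' returns the completed `exp_fit` with `R` and `p_R` fields added.
#'
#' @inheritParams fit_exponential
#' @param frequency Platform frequency in Hz for the seconds conversion.
#' @return A completed `exp_fit`.
#' @export
fit_adaptation <- function(y, n = NULL, frequency = NULL, tau_bounds = NULL,
                           tol_B = 0.02) {
  fit <- fit_exponential(y, n = n, tau_bounds = tau_bounds, tol_B = tol_B)
  fit <- derive_indices(fit, frequency = frequency)
  gof <- goodness_of_fit(fit)
  fit$R <- gof$R
  fit$p_R <- gof$p
  fit
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> y = A + B*exp(-C*t), t = cycle - 1\n")
  cat(sprintf("  A = %.4g, B = %.4g, C = %.4g, rss = %.4g%s\n",
              x$A, x$B, x$C, x$rss,
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  if (!is.null(x$tau_cycles)) {
    cat(sprintf("  tau = %.4g cycles%s, I = %.4g, AI = %.4g\n",
                x$tau_cycles,
                if (!is.na(x$tau_seconds)) {
                  sprintf(" (%.4g s)", x$tau_seconds)
                } else "",
                x$I, x$AI))
  }
  if (!is.null(x$R)) {
    cat(sprintf("  goodness R = %.3f (p = %.3g)\n", x$R, x$p_R))
  }
  invisible(x)
}

#' Steady-state summary of a per-cycle series
#'
#' Means of the per-cycle PP displacement and mean AP position over the
#' steady-state window (cycles 15-27 by default, justified by
#' `3 * tau < 15` cycles for the fitted time constants), together with the
#' mean over the first `initial_k` cycles for comparison with the initial
#' state.
#'
#' @param series A `cycle_series` from [per_cycle_metrics()].
#' @param window Cycle range, as `c(first, last)`.
#' @param initial_k Number of initial cycles averaged for the comparison
#'   value.
#' @return List with `window`, `mean_pp`, `mean_ap`, `initial_pp`,
#'   `initial_ap`.
#' @export
steady_state <- function(series, window = c(15, 27), initial_k = 1) {
  stopifnot(inherits(series, "cycle_series"), length(window) == 2L)
  sel <- series$cycle >= window[1] & series$cycle <= window[2]
  if (!any(series$cycle == window[1]) || !any(series$cycle == window[2])) {
    stop("steady-state window [", window[1], ", ", window[2],
         "] outside the available cycles", call. = FALSE)
  }
  ini <- series$cycle <= initial_k
  list(window = window,
       mean_pp = mean(series$pp[sel]),
       mean_ap = mean(series$mean_ap[sel]),
       initial_pp = mean(series$pp[ini]),
       initial_ap = mean(series$mean_ap[ini]))
}

#' Average per-cycle series across trials
#'
#' Element-wise mean of `pp` and `mean_ap` across repeated trials of the
#' same condition (the protocol averages the two trials per condition
#' before fitting).
#'
#' @param series_list List of `cycle_series` with identical segment and
#'   cycle count.
#' @return A single averaged `cycle_series`.
#' @export
average_trials <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  lens <- vapply(series_list, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("mismatched cycle counts across trials: ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  segs <- unique(vapply(series_list, function(s) s$segment[1], character(1)))
  if (length(segs) != 1L) {
    stop("cannot average series from different segments: ",
         paste(segs, collapse = ", "), call. = FALSE)
  }
  out <- series_list[[1]]
  out$pp <- rowMeans(vapply(series_list, `[[`, numeric(lens[1]), "pp"))
  out$mean_ap <- rowMeans(vapply(series_list, `[[`, numeric(lens[1]),
                                 "mean_ap"))
  out
}
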