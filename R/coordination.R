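# Head-pelvis coordination: the lag-0 cross-correlation coefficient of the
# two within-cycle traces after mean-centering (i.e. the Pearson r of the
# two windows). Positive = segments move in the same direction. The course
# of the coefficient across cycles is fitted with the same exponential
# model as the PP data, and the coefficient is regressed against head PP.

#' Lag-0 head-pelvis cross-correlation per cycle
#'
#' For each cycle window, the Pearson correlation between the within-cycle
#' head and pelvis traces (each centred on its within-cycle mean): the
#' lag-0 normalized cross-covariance. A cycle in which either trace has
#' zero variance yields `NA`, flagged in the `undefined` column. Fisher
#' z-transformed values are included for averaging across trials.
#'
#' @param rec A [trial_recording()].
#' @param windows Cycle windows from [segment_cycles()].
#' @return A tibble of class `cc_series` with columns `cycle`, `cc`, `z`,
#'   `undefined`.
#' @export
cc_per_cycle <- function(rec, windows) {
  stopifnot(inherits(rec, "trial_recording"), nrow(windows) >= 1)
  hx <- rec$head_ap
  px <- rec$pelvis_ap
  cc <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- windows$start_sample[i]:(windows$end_sample[i] - 1L)
    h <- hx[idx]
    p <- px[idx]
    if (sd(h) > 0 && sd(p) > 0) cc[i] <- cor(h, p)
  }
  out <- tibble(
    cycle = windows$cycle,
    cc = cc,
    z = fisher_z(cc),
    undefined = is.na(cc)
  )
  attr(out, "frequency") <- attr(windows, "frequency")
  class(out) <- c("cc_series", class(out))
  out
}

#' Fit the exponential model to the cross-correlation course
#'
#' Delegates to [fit_adaptation()] on the per-cycle correlation
#' coefficients (cycles with undefined coefficients are dropped, keeping
#' their cycle indices), so time constant, intercept and adaptation index
#' follow the same conventions as the PP fits.
#'
#' @param ccs A `cc_series` from [cc_per_cycle()] (or a numeric vector of
#'   per-cycle coefficients).
#' @param frequency Platform frequency in Hz for the seconds conversion.
#' @inheritParams fit_exponential
#' @return A completed `exp_fit`.
#' @export
fit_cc_course <- function(ccs, frequency = NULL, tau_bounds = NULL,
                          tol_B = 0.02) {
  if (inherits(ccs, "cc_series")) {
    if (is.null(frequency)) frequency <- attr(ccs, "frequency")
    keep <- !is.na(ccs$cc)
    y <- ccs$cc[keep]
    n <- ccs$cycle[keep]
  } else {
    y <- as.numeric(ccs)
    n <- seq_along(y)
  }
  if (length(y) < 5L) {
    stop("need at least 5 cycles of defined correlation to fit the course",
         call. = FALSE)
  }
  fit_adaptation(y, n = n, frequency = frequency, tau_bounds = tau_bounds,
                 tol_B = tol_B)
}

#' Regress the cross-correlation coefficient on head PP displacement
#'
#' Ordinary least-squares line `cc = slope * pp + intercept` across cycles,
#' with the coefficient of determination R^2 and the two-tailed p-value of
#' the slope, mirroring the condition-level association between
#' coordination and head displacement.
#'
#' @param ccs A `cc_series` (or numeric vector of per-cycle coefficients).
#' @param pps A head `cycle_series` (or numeric vector of per-cycle PP
#'   values), same cycle count.
#' @return A tibble of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `p`, `n`.
#' @export
cc_vs_pp_regression <- function(ccs, pps) {
  cc <- if (inherits(ccs, "cc_series")) ccs$cc else as.numeric(ccs)
  pp <- if (inherits(pps, "cycle_series")) pps$pp else as.numeric(pps)
  if (length(cc) != length(pp)) {
    stop("cc and pp series must have the same number of cycles",
         call. = FALSE)
  }
  keep <- is.finite(cc) & is.finite(pp)
  cc <- cc[keep]
  pp <- pp[keep]
  if (length(cc) < 3L) {
    stop("need at least 3 cycles for the regression", call. = FALSE)
  }
  if (sd(pp) == 0) {
    stop("undefined slope: PP series has zero variance", call. = FALSE)
  }
  fit <- lm(cc ~ pp)
  # summary() warns on numerically perfect fits, which are legitimate here
  sm <- suppressWarnings(summary(fit))
  out <- tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p = unname(sm$coefficients[2, 4]),
    n = length(cc)
  )
  class(out) <- c("regression_result", class(out))
  out
}
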