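# End-to-end orchestration: synthesize (or load) a cohort, segment every
# trial, extract per-cycle metrics, average the repeated trials of each
# condition, fit the adaptation model and the coordination course, and
# summarize at condition level. In synthetic mode a recovery report joins
# the estimates to the generator's ground truth.

#' Default per-condition generator parameterization
#'
#' One row per visual condition x frequency cell of the standard protocol
#' (EO, EO-TP, EO-TG, EC at 0.18 Hz and 0.56 Hz). Time constants and
#' adaptation indices follow the group means reported for this protocol
#' (e.g. pelvis EO 1.47 vs EC 3.47 cycles at LF; head EC AI -0.16 at HF);
#' steady-state amplitudes and coordination levels follow the reported
#' condition-level regressions. See the methods vignette for the full
#' rationale of each value.
#'
#' @return A tibble with columns `condition`, `frequency`, per-segment
#'   `A`/`AI`/`tau`, and coordination `cc_A`/`cc_I`/`cc_tau`.
#' @export
condition_defaults <- function() {
  tb <- tibble::tribble(
    ~condition, ~frequency, ~head_A, ~head_AI, ~head_tau,
                            ~pelvis_A, ~pelvis_AI, ~pelvis_tau,
                            ~cc_A, ~cc_I, ~cc_tau,
    "EO",    0.18,  9.2, 0.080, 1.84,  8.5, 0.060, 1.47, 0.98, 0.93, 1.5,
    "EO-TP", 0.18, 10.2, 0.150, 3.50,  9.0, 0.078, 3.16, 0.97, 0.90, 1.8,
    "EO-TG", 0.18,  9.3, 0.150, 3.50,  8.6, 0.090, 3.02, 0.97, 0.90, 1.8,
    "EC",    0.18, 10.8, 0.200, 3.50,  9.5, 0.120, 3.47, 0.95, 0.86, 2.0,
    "EO",    0.56,  5.5, -0.300, 2.00, 6.5, -0.050, 1.50, 0.55, 0.75, 4.0,
    "EO-TP", 0.56,  4.3, -0.300, 2.50, 6.3,  0.010, 1.80, 0.30, 0.55, 4.0,
    "EO-TG", 0.56,  3.9, -0.300, 2.50, 6.2,  0.005, 1.80, 0.35, 0.60, 4.0,
    "EC",    0.56,  5.8, -0.160, 2.20, 7.5, -0.050, 1.60, 0.60, 0.80, 4.0
  )
  tb
}

intercept_from_ai <- function(A, AI) A * (1 - AI) / (1 + AI)

#' Build synthetic configurations from a condition table
#'
#' Turns one row of [condition_defaults()] (or a table in the same layout)
#' into a [synth_config()]; intercepts are derived from the asymptote and
#' adaptation index as `I = A (1 - AI)/(1 + AI)`.
#'
#' @param conditions A tibble in the layout of [condition_defaults()].
#' @param ... Overrides passed to every [synth_config()] (e.g. `noise_sd`).
#' @return A list of `synth_config`, one per row.
#' @export
condition_configs <- function(conditions = condition_defaults(), ...) {
  lapply(seq_len(nrow(conditions)), function(i) {
    r <- conditions[i, ]
    synth_config(
      frequency = r$frequency,
      head = pp_envelope(r$head_A, intercept_from_ai(r$head_A, r$head_AI),
                         r$head_tau),
      pelvis = pp_envelope(r$pelvis_A,
                           intercept_from_ai(r$pelvis_A, r$pelvis_AI),
                           r$pelvis_tau),
      coordination = cc_course(A = r$cc_A, I = r$cc_I, tau = r$cc_tau),
      visual_condition = r$condition,
      ...
    )
  })
}

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read trial
#'   TSVs).
#' @param conditions Condition table for synthetic mode, as
#'   [condition_defaults()].
#' @param n_subjects,n_trials,jitter_sd Cohort layout, see
#'   [generate_cohort()].
#' @param files Character vector of trial file paths (files mode).
#' @param max_cycles Truncate every trial to this many cycles (the common
#'   analysis length across frequencies).
#' @param steady_window Steady-state cycle range `c(first, last)`.
#' @param onset_k Threshold multiplier for [detect_onset()].
#' @param noise_sd Measurement-noise override passed to the generator;
#'   `NULL` uses the generator default (5% of each segment's asymptote).
#' @param out_dir If non-`NULL`, results tables and a provenance record are
#'   written there as TSV/JSON.
#' @param seed Integer seed (mandatory in synthetic mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            conditions = condition_defaults(),
                            n_subjects = 20, n_trials = 2, jitter_sd = 0.15,
                            files = NULL,
                            max_cycles = 27, steady_window = c(15, 27),
                            onset_k = 5, noise_sd = NULL,
                            out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed)) {
    stop("seed is mandatory in synthetic mode", call. = FALSE)
  }
  if (mode == "files" && length(files) == 0L) {
    stop("files mode needs at least one trial file", call. = FALSE)
  }
  structure(
    list(mode = mode, conditions = conditions, n_subjects = n_subjects,
         n_trials = n_trials, jitter_sd = jitter_sd, files = files,
         max_cycles = max_cycles, steady_window = steady_window,
         onset_k = onset_k, noise_sd = noise_sd, out_dir = out_dir,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full adaptation-analysis pipeline
#'
#' Synthesizes or loads a cohort of trials; per trial: detects onset,
#' segments cycles (truncated to `max_cycles`), extracts per-cycle PP and
#' mean AP position for head and pelvis, and the per-cycle head-pelvis
#' cross-correlation. The repeated trials of each (subject, condition,
#' frequency) are averaged per cycle (PP and position element-wise,
#' correlations through the Fisher z-transform), then the exponential
#' adaptation model is fitted to the averaged PP series of each segment and
#' to the averaged correlation course. Condition-level summaries mirror the
#' protocol's reporting: a one-sample t-test of the adaptation index
#' against zero, a paired t-test of steady-state vs initial mean AP
#' position, the Spearman correlation between the across-subject cycle
#' means of head position and head PP, and the OLS regression of the cycle
#' means of the correlation coefficient on head PP. Trials that fail at any
#' stage are tallied in `failures` and the remaining trials continue.
#'
#' @param cfg A [pipeline_config()].
#' @return List of tibbles: `fits` (one row per subject x condition x
#'   frequency x segment), `cc_fits`, `cycle_means`, `ai_tests`,
#'   `position_tests`, `spearman_pp_position`, `cc_regressions`,
#'   `recovery` (synthetic mode), `failures`, and `provenance`. Written to
#'   `out_dir` as TSV/JSON when configured.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))

  if (cfg$mode == "synthetic") {
    configs <- condition_configs(cfg$conditions, noise_sd = cfg$noise_sd)
    cohort <- generate_cohort(configs, n_subjects = cfg$n_subjects,
                              n_trials = cfg$n_trials,
                              jitter_sd = cfg$jitter_sd, seed = cfg$seed)
    trials <- cohort$trials
    truth <- cohort$truth
  } else {
    trials <- lapply(cfg$files, read_trial)
    truth <- NULL
  }

  failures <- list()
  per_trial <- list()
  for (i in seq_along(trials)) {
    rec <- trials[[i]]
    res <- tryCatch({
      onset <- detect_onset(rec, k = cfg$onset_k)
      win <- segment_cycles(rec, onset, max_cycles = cfg$max_cycles)
      list(
        key = tibble(subject = rec$subject_id,
                     condition = rec$visual_condition,
                     frequency = rec$frequency,
                     trial = rec$trial_index),
        head = per_cycle_metrics(rec, win, "head"),
        pelvis = per_cycle_metrics(rec, win, "pelvis"),
        cc = cc_per_cycle(rec, win)
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble(
        subject = rec$subject_id, condition = rec$visual_condition,
        frequency = rec$frequency, trial = rec$trial_index,
        stage = "per-trial", message = conditionMessage(res))
    } else {
      per_trial[[length(per_trial) + 1L]] <- res
    }
  }
  if (length(per_trial) == 0L) {
    stop("every trial failed; first failure: ", failures[[1]]$message,
         call. = FALSE)
  }

  keys <- dplyr::bind_rows(lapply(per_trial, `[[`, "key"))
  keys$idx <- seq_len(nrow(keys))
  groups <- split(keys$idx,
                  paste(keys$subject, keys$condition, keys$frequency,
                        sep = "\r"))

  fits <- list()
  cc_fits <- list()
  cycle_rows <- list()
  for (g in groups) {
    k1 <- per_trial[[g[1]]]$key
    res <- tryCatch({
      grp_fits <- list()
      for (seg in c("head", "pelvis")) {
        avg <- average_trials(lapply(g, function(i) per_trial[[i]][[seg]]))
        fit <- fit_adaptation(avg$pp, n = avg$cycle,
                              frequency = k1$frequency)
        ss <- steady_state(avg, window = cfg$steady_window)
        grp_fits[[seg]] <- list(avg = avg, fit = fit, ss = ss)
      }
      # average correlation courses through Fisher z
      zmat <- vapply(g, function(i) per_trial[[i]]$cc$z,
                     numeric(nrow(per_trial[[g[1]]]$cc)))
      cc_mean <- fisher_z_inv(rowMeans(as.matrix(zmat)))
      cc_fit <- fit_adaptation(cc_mean,
                               n = per_trial[[g[1]]]$cc$cycle,
                               frequency = k1$frequency)
      list(grp_fits = grp_fits, cc_mean = cc_mean, cc_fit = cc_fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble(
        subject = k1$subject, condition = k1$condition,
        frequency = k1$frequency, trial = NA_integer_,
        stage = "fit", message = conditionMessage(res))
      next
    }
    for (seg in c("head", "pelvis")) {
      f <- res$grp_fits[[seg]]$fit
      ss <- res$grp_fits[[seg]]$ss
      fits[[length(fits) + 1L]] <- tibble(
        subject = k1$subject, condition = k1$condition,
        frequency = k1$frequency, segment = seg,
        A = f$A, B = f$B, C = f$C,
        tau_cycles = f$tau_cycles, tau_seconds = f$tau_seconds,
        I = f$I, AI = f$AI, R = f$R, p_R = f$p_R,
        degenerate = f$degenerate,
        ss_pp = ss$mean_pp, ss_ap = ss$mean_ap,
        initial_pp = ss$initial_pp, initial_ap = ss$initial_ap)
      avg <- res$grp_fits[[seg]]$avg
      cycle_rows[[length(cycle_rows) + 1L]] <- tibble(
        subject = k1$subject, condition = k1$condition,
        frequency = k1$frequency, segment = seg, cycle = avg$cycle,
        pp = avg$pp, mean_ap = avg$mean_ap,
        cc = if (seg == "head") res$cc_mean else NA_real_)
    }
    f <- res$cc_fit
    cc_fits[[length(cc_fits) + 1L]] <- tibble(
      subject = k1$subject, condition = k1$condition,
      frequency = k1$frequency, segment = "head-pelvis",
      A = f$A, B = f$B, C = f$C,
      tau_cycles = f$tau_cycles, tau_seconds = f$tau_seconds,
      I = f$I, AI = f$AI, R = f$R, p_R = f$p_R,
      degenerate = f$degenerate,
      mean_cc = fisher_z_inv(mean(fisher_z(res$cc_mean))))
  }

  fits <- dplyr::bind_rows(fits)
  cc_fits <- dplyr::bind_rows(cc_fits)
  cycle_means <- dplyr::bind_rows(cycle_rows)

  # condition-level summaries
  ai_tests <- fits |>
    dplyr::group_by(.data$condition, .data$frequency, .data$segment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_AI = mean(.data$AI),
      t = if (dplyr::n() >= 2) one_sample_t(.data$AI)$statistic else NA_real_,
      p = if (dplyr::n() >= 2) one_sample_t(.data$AI)$p else NA_real_,
      .groups = "drop")

  position_tests <- fits |>
    dplyr::group_by(.data$condition, .data$frequency, .data$segment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_shift = mean(.data$ss_ap - .data$initial_ap),
      t = if (dplyr::n() >= 2) {
        paired_t(.data$ss_ap, .data$initial_ap)$statistic
      } else NA_real_,
      p = if (dplyr::n() >= 2) {
        paired_t(.data$ss_ap, .data$initial_ap)$p
      } else NA_real_,
      .groups = "drop")

  cond_cycle_means <- cycle_means |>
    dplyr::filter(.data$segment == "head") |>
    dplyr::group_by(.data$condition, .data$frequency, .data$cycle) |>
    dplyr::summarise(pp = mean(.data$pp), mean_ap = mean(.data$mean_ap),
                     cc = fisher_z_inv(mean(fisher_z(.data$cc))),
                     .groups = "drop")

  spearman_pp_position <- cond_cycle_means |>
    dplyr::group_by(.data$condition, .data$frequency) |>
    dplyr::group_modify(~ spearman_cor(.x$mean_ap, .x$pp)) |>
    dplyr::ungroup()

  cc_regressions <- cond_cycle_means |>
    dplyr::group_by(.data$condition, .data$frequency) |>
    dplyr::group_modify(~ as_tibble(cc_vs_pp_regression(.x$cc, .x$pp))) |>
    dplyr::ungroup()

  recovery <- if (!is.null(truth)) recovery_report(fits, truth) else NULL

  provenance <- list(
    package = "posturadapt",
    version = as.character(utils::packageVersion("posturadapt")),
    r_version = R.version.string,
    mode = cfg$mode,
    seed = cfg$seed,
    n_subjects = cfg$n_subjects, n_trials = cfg$n_trials,
    jitter_sd = cfg$jitter_sd, max_cycles = cfg$max_cycles,
    steady_window = cfg$steady_window,
    n_trials_processed = length(per_trial),
    n_failures = length(failures))

  out <- list(fits = fits, cc_fits = cc_fits, cycle_means = cycle_means,
              ai_tests = ai_tests, position_tests = position_tests,
              spearman_pp_position = spearman_pp_position,
              cc_regressions = cc_regressions,
              recovery = recovery,
              failures = dplyr::bind_rows(failures),
              provenance = provenance)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(fits, file.path(cfg$out_dir, "fits.tsv"))
    write_results(cc_fits, file.path(cfg$out_dir, "cc_fits.tsv"))
    write.table(cycle_means, file.path(cfg$out_dir, "cycle_means.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("ai_tests", "position_tests", "spearman_pp_position",
                 "cc_regressions")) {
      write.table(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(recovery)) {
      write.table(recovery$per_fit,
                  file.path(cfg$out_dir, "recovery_per_fit.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(recovery$summary,
                  file.path(cfg$out_dir, "recovery_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Join fitted parameters to the generator's ground truth
#'
#' For every (subject, condition, frequency, segment) fit, the bias and
#' relative error of the estimated asymptote, intercept, time constant and
#' adaptation index against the generative values, plus a per-parameter
#' summary (median bias and median absolute relative error).
#'
#' @param estimates `fits` table from [run_pipeline()].
#' @param truth `truth` table from [generate_cohort()].
#' @return List with `per_fit` and `summary` tibbles.
#' @export
recovery_report <- function(estimates, truth) {
  key <- c("subject", "condition", "frequency", "segment")
  joined <- dplyr::inner_join(estimates, truth, by = key,
                              suffix = c("_est", "_true"))
  if (nrow(joined) != nrow(estimates)) {
    stop("key mismatch between estimates and ground truth (",
         nrow(estimates) - nrow(joined), " fits without truth rows)",
         call. = FALSE)
  }
  per_fit <- list()
  for (par in c("A", "I", "AI")) {
    per_fit[[par]] <- tibble(
      joined[key], parameter = par,
      truth = joined[[paste0(par, "_true")]],
      estimate = joined[[paste0(par, "_est")]])
  }
  per_fit$tau <- tibble(
    joined[key], parameter = "tau",
    truth = joined$tau, estimate = joined$tau_cycles)
  per_fit <- dplyr::bind_rows(per_fit)
  per_fit$bias <- per_fit$estimate - per_fit$truth
  per_fit$rel_error <- per_fit$bias /
    ifelse(abs(per_fit$truth) > 0, abs(per_fit$truth), NA_real_)
  summary <- per_fit |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_bias = median(.data$bias, na.rm = TRUE),
      median_abs_rel_error = median(abs(.data$rel_error), na.rm = TRUE),
      .groups = "drop")
  list(per_fit = per_fit, summary = summary)
}
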