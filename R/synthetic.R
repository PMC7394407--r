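# Synthetic trial generator. Emulates the standard protocol: a quiet-stance
# pre-period on the still platform, then a train of sinusoidal AP platform
# translations (10 cm peak-to-peak) at 0.18 Hz (LF, 27 cycles) or 0.56 Hz
# (HF, 31 cycles), sampled at 140 Hz. Head and pelvis traces oscillate with
# the platform under a per-cycle peak-to-peak envelope
#   G(n) = A + (I - A) * exp(-(n - 1) / tau)
# (A = asymptote, I = intercept at cycle 1, tau in cycles), the same
# three-parameter exponential the analysis fits, so the generator's
# parameters are the ground truth of recovery studies.

#' Per-cycle peak-to-peak envelope
#'
#' Parameterizes the exponential adaptation envelope by asymptote `A`,
#' intercept `I` (both cm, the quantities the analysis reports) and time
#' constant `tau` (cycles). Internally the fitted model's `B = I - A` and
#' `C = 1/tau`.
#'
#' @param A Asymptotic peak-to-peak amplitude, cm (> 0).
#' @param I Peak-to-peak amplitude at the first cycle, cm (> 0).
#' @param tau Time constant in cycles (> 0).
#' @return A `pp_envelope` list.
#' @export
pp_envelope <- function(A, I, tau) {
  stopifnot(is.numeric(A), is.numeric(I), is.numeric(tau))
  if (A <= 0 || I <= 0 || tau <= 0) {
    stop("invalid envelope: A, I and tau must all be > 0", call. = FALSE)
  }
  structure(list(A = A, I = I, tau = tau), class = "pp_envelope")
}

#' @rdname pp_envelope
#' @param env A `pp_envelope`.
#' @param n Cycle index (1-based); vectorized.
#' @return `envelope_at()`: the envelope value `G(n)` in cm.
#' @export
envelope_at <- function(env, n) {
  env$A + (env$I - env$A) * exp(-(n - 1) / env$tau)
}

#' Head-pelvis coordination course
#'
#' The per-cycle shared-variance fraction lambda of the two segments'
#' oscillatory components; the expected lag-0 per-cycle cross-correlation of
#' the noiseless traces equals lambda. Either a constant, or an exponential
#' course with the same (A, I, tau) parameterization as [pp_envelope()] so
#' the coordination analysis can recover it.
#'
#' @param A Asymptotic lambda in `[0, 1]`.
#' @param I Lambda at the first cycle, in `[0, 1]`.
#' @param tau Time constant in cycles (> 0), or `NULL` for a constant course
#'   (then `I` is ignored).
#' @return A `cc_course` list.
#' @export
cc_course <- function(A, I = A, tau = NULL) {
  stopifnot(A >= 0, A <= 1, I >= 0, I <= 1)
  if (!is.null(tau)) stopifnot(tau > 0)
  structure(list(A = A, I = I, tau = tau), class = "cc_course")
}

lambda_at <- function(course, n) {
  if (is.null(course$tau)) {
    rep(course$A, length(n))
  } else {
    course$A + (course$I - course$A) * exp(-(n - 1) / course$tau)
  }
}

#' Configuration of a synthetic trial
#'
#' Collects every generative parameter of one synthetic trial. Defaults are
#' the standard protocol: 0.18 Hz translation, 27 cycles, 140 Hz sampling,
#' 10 cm platform peak-to-peak amplitude, a 5 s quiet-stance pre-period and
#' a 1 s still post-period.
#'
#' @param frequency Platform translation frequency, Hz.
#' @param n_cycles Number of full translation cycles; defaults to the
#'   protocol count (27 at 0.18 Hz, 31 at 0.56 Hz).
#' @param sampling_rate Sampling rate, Hz.
#' @param platform_pp Platform peak-to-peak amplitude, cm.
#' @param pre_period Quiet-stance period before the first translation, s.
#' @param post_period Still period after the last cycle, s.
#' @param head,pelvis [pp_envelope()] of each segment.
#' @param phase_head,phase_pelvis Phase offset of each segment's
#'   oscillation relative to the platform, radians.
#' @param mean_drift Total drift of the mean AP position across the
#'   perturbation period, cm (linear ramp; 0 = stationary mean).
#' @param coordination A [cc_course()], or a single number in `[0, 1]`
#'   (constant shared-variance fraction).
#' @param noise_sd Additive white Gaussian measurement noise SD, cm. A
#'   single number applies to both segments; `NULL` defaults to 5% of each
#'   segment's asymptote `A`.
#' @param seed Integer seed; if non-`NULL` the trial is a pure function of
#'   the configuration (the caller's RNG state is restored afterwards).
#' @param subject_id,visual_condition,trial_index Metadata passed to the
#'   [trial_recording()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(frequency = 0.18,
                         n_cycles = NULL,
                         sampling_rate = 140,
                         platform_pp = 10,
                         pre_period = 5,
                         post_period = 1,
                         head = pp_envelope(A = 10, I = 8, tau = 1.84),
                         pelvis = pp_envelope(A = 9, I = 7.4, tau = 1.47),
                         phase_head = 0,
                         phase_pelvis = 0,
                         mean_drift = 0,
                         coordination = 1,
                         noise_sd = NULL,
                         seed = NULL,
                         subject_id = "S01",
                         visual_condition = "EO",
                         trial_index = 1L) {
  if (is.null(n_cycles)) {
    n_cycles <- if (isTRUE(all.equal(frequency, 0.56))) 31L else 27L
  }
  stopifnot(frequency > 0, n_cycles >= 1, platform_pp > 0,
            pre_period >= 0, post_period >= 0)
  if (sampling_rate <= 2 * frequency) {
    stop("sampling_rate must exceed twice the platform frequency",
         call. = FALSE)
  }
  if (is.numeric(coordination) && !inherits(coordination, "cc_course")) {
    coordination <- cc_course(A = coordination)
  }
  stopifnot(inherits(head, "pp_envelope"), inherits(pelvis, "pp_envelope"),
            inherits(coordination, "cc_course"))
  if (is.null(noise_sd)) {
    noise_sd <- c(head = 0.05 * head$A, pelvis = 0.05 * pelvis$A)
  } else if (length(noise_sd) == 1L) {
    noise_sd <- c(head = noise_sd, pelvis = noise_sd)
  }
  stopifnot(all(noise_sd >= 0))
  structure(
    list(frequency = frequency, n_cycles = as.integer(n_cycles),
         sampling_rate = sampling_rate, platform_pp = platform_pp,
         pre_period = pre_period, post_period = post_period,
         head = head, pelvis = pelvis,
         phase_head = phase_head, phase_pelvis = phase_pelvis,
         mean_drift = mean_drift, coordination = coordination,
         noise_sd = noise_sd, seed = seed,
         subject_id = subject_id, visual_condition = visual_condition,
         trial_index = as.integer(trial_index)),
    class = "synth_config"
  )
}

synth_time_grid <- function(cfg) {
  total <- cfg$pre_period + cfg$n_cycles / cfg$frequency + cfg$post_period
  n <- floor(total * cfg$sampling_rate) + 1L
  (seq_len(n) - 1L) / cfg$sampling_rate
}

synth_platform_trace <- function(cfg, time) {
  tp <- time - cfg$pre_period
  dur <- cfg$n_cycles / cfg$frequency
  active <- tp >= 0 & tp < dur
  plat <- numeric(length(time))
  plat[active] <- (cfg$platform_pp / 2) * sin(2 * pi * cfg$frequency * tp[active])
  plat
}

#' Generate the platform trace of a synthetic trial
#'
#' Zeros (still platform, at the midline) during the pre-period, then
#' `n_cycles` full sinusoidal periods of peak-to-peak amplitude
#' `platform_pp` with positive-going onset, then a still post-period back at
#' the midline. The head and pelvis traces of the returned recording are
#' copies of the platform trace: a rigid-body record that serves as a
#' negative control for the adaptation analysis (PP constant, no
#' adaptation, cross-correlation 1).
#'
#' @param cfg A [synth_config()].
#' @return A [trial_recording()].
#' @export
generate_platform <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  time <- synth_time_grid(cfg)
  plat <- synth_platform_trace(cfg, time)
  trial_recording(time, plat, plat, plat,
                  sampling_rate = cfg$sampling_rate,
                  subject_id = cfg$subject_id,
                  visual_condition = cfg$visual_condition,
                  frequency = cfg$frequency,
                  trial_index = cfg$trial_index)
}

#' Generate a synthetic trial
#'
#' Builds head and pelvis AP traces as
#' \deqn{x(t) = M(t) + \frac{G(n(t))}{2\sqrt{2}}\,o(t) + \epsilon(t)}
#' where `G(n)` is the segment's peak-to-peak envelope evaluated at the
#' cycle index `n(t)` (piecewise constant: amplitude changes at cycle
#' boundaries), `M(t)` the (possibly linearly drifting) mean position,
#' `epsilon` white Gaussian measurement noise, and the unit-variance
#' oscillatory component
#' \deqn{o(t) = \sqrt{\lambda(n)}\,\sqrt{2}\sin(2\pi f t' + \phi) +
#'       \sqrt{1-\lambda(n)}\, w(t)}
#' mixes a sinusoid shared between the segments with a segment-specific
#' independent sway process `w` (unit-variance band-limited Gaussian noise,
#' AR(1) with ~2 Hz bandwidth, emulating uncoordinated postural sway
#' rather than wide-band sensor noise). The shared-variance fraction
#' `lambda(n)` is the configured
#' coordination course, so the expected lag-0 per-cycle head-pelvis
#' correlation of the noiseless traces equals `lambda(n)` (attenuated by
#' measurement noise; see [expected_cc()]). With `noise_sd = 0` and
#' `lambda = 1` the measured per-cycle PP of each segment equals `G(n)` up
#' to sampling discretization.
#'
#' @param cfg A [synth_config()].
#' @return A [trial_recording()] with attribute `"truth"`: a tibble of the
#'   generative ground truth (per-segment A, I, tau, AI, and the
#'   coordination course) for recovery studies.
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(cfg$seed)
  }

  time <- synth_time_grid(cfg)
  plat <- synth_platform_trace(cfg, time)
  tp <- time - cfg$pre_period
  dur <- cfg$n_cycles / cfg$frequency
  active <- tp >= 0 & tp < dur
  n_samp <- length(time)

  cyc <- pmin(pmax(floor(tp * cfg$frequency) + 1, 1), cfg$n_cycles)
  lam_n <- pmin(pmax(lambda_at(cfg$coordination, seq_len(cfg$n_cycles)), 0), 1)
  lam <- lam_n[cyc]

  # mean position: 0 during pre-period, linear ramp to mean_drift across the
  # perturbation, held afterwards
  M <- numeric(n_samp)
  M[active] <- cfg$mean_drift * (tp[active] / dur)
  M[tp >= dur] <- cfg$mean_drift

  # unit-variance AR(1) with ~2 Hz bandwidth: independent postural sway
  ar_sway <- function(n) {
    phi <- exp(-2 * pi * 2 / cfg$sampling_rate)
    as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - phi^2)), phi,
                             method = "recursive"))
  }

  seg_trace <- function(env, phase, sd_eps) {
    shared <- sqrt(2) * sin(2 * pi * cfg$frequency * tp + phase)
    w <- ar_sway(n_samp)
    osc <- sqrt(lam) * shared + sqrt(1 - lam) * w
    G <- envelope_at(env, cyc)
    x <- M
    x[active] <- x[active] + (G[active] / (2 * sqrt(2))) * osc[active]
    if (sd_eps > 0) x <- x + rnorm(n_samp, 0, sd_eps)
    x
  }

  head_ap <- seg_trace(cfg$head, cfg$phase_head, cfg$noise_sd[["head"]])
  pelvis_ap <- seg_trace(cfg$pelvis, cfg$phase_pelvis, cfg$noise_sd[["pelvis"]])

  rec <- trial_recording(time, plat, head_ap, pelvis_ap,
                         sampling_rate = cfg$sampling_rate,
                         subject_id = cfg$subject_id,
                         visual_condition = cfg$visual_condition,
                         frequency = cfg$frequency,
                         trial_index = cfg$trial_index)
  attr(rec, "truth") <- synth_truth(cfg)
  rec
}

ai_of <- function(A, I) (A - I) / (A + I)

synth_truth <- function(cfg) {
  env <- list(head = cfg$head, pelvis = cfg$pelvis)
  tibble(
    subject = cfg$subject_id,
    condition = cfg$visual_condition,
    frequency = cfg$frequency,
    segment = c("head", "pelvis"),
    A = unname(vapply(env, `[[`, numeric(1), "A")),
    I = unname(vapply(env, `[[`, numeric(1), "I")),
    tau = unname(vapply(env, `[[`, numeric(1), "tau")),
    AI = ai_of(A, I),
    cc_A = cfg$coordination$A,
    cc_I = cfg$coordination$I,
    cc_tau = cfg$coordination$tau %||% NA_real_
  )
}

#' Expected per-cycle head-pelvis cross-correlation of a synthetic trial
#'
#' Closed-form expectation under the generative variance decomposition: the
#' shared sinusoid contributes covariance `lambda * sd_h * sd_p` (with
#' `sd_seg = G_seg/(2*sqrt(2))`, the within-cycle SD of the oscillatory
#' component), attenuated by each segment's additive measurement noise and
#' by any phase offset between the segments.
#'
#' @param cfg A [synth_config()].
#' @param n Cycle indices (default all cycles).
#' @return Numeric vector of expected lag-0 correlations per cycle.
#' @export
expected_cc <- function(cfg, n = seq_len(cfg$n_cycles)) {
  lam <- pmin(pmax(lambda_at(cfg$coordination, n), 0), 1)
  sd_h <- envelope_at(cfg$head, n) / (2 * sqrt(2))
  sd_p <- envelope_at(cfg$pelvis, n) / (2 * sqrt(2))
  num <- lam * sd_h * sd_p * cos(cfg$phase_head - cfg$phase_pelvis)
  den <- sqrt((sd_h^2 + cfg$noise_sd[["head"]]^2) *
              (sd_p^2 + cfg$noise_sd[["pelvis"]]^2))
  num / den
}

#' Generate a synthetic cohort
#'
#' Replicates the study layout: `n_subjects` participants each performing
#' `n_trials` trials under every configuration in `configs` (one per visual
#' condition x frequency). Inter-individual variability is emulated by
#' jittering each subject's envelope parameters (A, I, tau of head and
#' pelvis) with independent log-normal multipliers of log-SD `jitter_sd`;
#' both trials of a subject share the subject's true parameters, as in a
#' repeated-measures design.
#'
#' @param configs A list of [synth_config()] (or a single one), one per
#'   condition cell; each config's `subject_id`/`trial_index` are
#'   overwritten.
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject and condition (protocol: 2).
#' @param jitter_sd Log-SD of the per-subject parameter multipliers; 0
#'   makes all subjects identical.
#' @param seed Integer seed for the whole cohort.
#' @return A list with `trials` (list of [trial_recording()]) and `truth`
#'   (tibble of per subject x condition x segment ground-truth parameters).
#' @export
generate_cohort <- function(configs, n_subjects = 20, n_trials = 2,
                            jitter_sd = 0.15, seed = 1) {
  if (inherits(configs, "synth_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1, n_trials >= 1, n_subjects >= 1,
            jitter_sd >= 0)
  set.seed(seed)

  trials <- list()
  truth <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (cfg in configs) {
      jit <- function(x) x * exp(rnorm(1, 0, jitter_sd))
      head_s <- pp_envelope(jit(cfg$head$A), jit(cfg$head$I), jit(cfg$head$tau))
      pelvis_s <- pp_envelope(jit(cfg$pelvis$A), jit(cfg$pelvis$I),
                              jit(cfg$pelvis$tau))
      for (k in seq_len(n_trials)) {
        cfg_sk <- cfg
        cfg_sk$head <- head_s
        cfg_sk$pelvis <- pelvis_s
        cfg_sk$subject_id <- sid
        cfg_sk$trial_index <- as.integer(k)
        cfg_sk$seed <- sample.int(.Machine$integer.max, 1)
        trials[[length(trials) + 1L]] <- generate_trial(cfg_sk)
      }
      cfg_truth <- cfg
      cfg_truth$head <- head_s
      cfg_truth$pelvis <- pelvis_s
      cfg_truth$subject_id <- sid
      truth[[length(truth) + 1L]] <- synth_truth(cfg_truth)
    }
  }
  list(trials = trials, truth = dplyr::bind_rows(truth))
}
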