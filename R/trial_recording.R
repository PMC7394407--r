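#' Trial recording of platform, head and pelvis AP displacement
#'
#' A `trial_recording` holds one uniformly sampled trial: the antero-posterior
#' (AP) displacement of the support platform and of the head and pelvis
#' markers, in cm, positive forward. It is the unit of analysis for cycle
#' segmentation ([segment_cycles()]) and all downstream per-cycle metrics.
#'
#' Invariants enforced at construction:
#' * all traces have the same length with no missing samples,
#' * `time` is strictly increasing with a constant step equal to
#'   `1/sampling_rate` within 1e-9 s,
#' * `sampling_rate` exceeds twice the perturbation frequency (Nyquist).
#'
#' @param time Sample times in seconds.
#' @param platform_ap,head_ap,pelvis_ap AP displacement traces in cm.
#' @param sampling_rate Sampling rate in Hz (140 Hz for the standard
#'   protocol).
#' @param subject_id Subject label.
#' @param visual_condition One of `"EO"` (eyes open), `"EO-TP"` (reading a
#'   text moving with the platform), `"EO-TG"` (reading a text fixed to the
#'   ground), `"EC"` (eyes closed).
#' @param frequency Platform translation frequency in Hz (0.18 = LF,
#'   0.56 = HF in the standard protocol).
#' @param trial_index Trial number within (subject, condition, frequency).
#'
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(time, platform_ap, head_ap, pelvis_ap,
                            sampling_rate,
                            subject_id = "S01",
                            visual_condition = c("EO", "EO-TP", "EO-TG", "EC"),
                            frequency = 0.18,
                            trial_index = 1L) {
  visual_condition <- match.arg(visual_condition)
  rec <- structure(
    list(
      time = as.numeric(time),
      platform_ap = as.numeric(platform_ap),
      head_ap = as.numeric(head_ap),
      pelvis_ap = as.numeric(pelvis_ap),
      sampling_rate = as.numeric(sampling_rate),
      subject_id = as.character(subject_id),
      visual_condition = visual_condition,
      frequency = as.numeric(frequency),
      trial_index = as.integer(trial_index)
    ),
    class = "trial_recording"
  )
  validate_trial_recording(rec)
}

#' @rdname trial_recording
#' @param rec A `trial_recording`.
#' @export
validate_trial_recording <- function(rec) {
  n <- length(rec$time)
  if (n == 0L) {
    stop("empty recording: no samples", call. = FALSE)
  }
  lens <- c(length(rec$platform_ap), length(rec$head_ap), length(rec$pelvis_ap))
  if (any(lens != n)) {
    stop("trace columns must all have the same length as `time` (",
         n, "); got ", paste(lens, collapse = "/"), call. = FALSE)
  }
  if (anyNA(rec$time) || anyNA(rec$platform_ap) ||
      anyNA(rec$head_ap) || anyNA(rec$pelvis_ap)) {
    stop("missing samples inside the record are not allowed", call. = FALSE)
  }
  if (!is.finite(rec$sampling_rate) || rec$sampling_rate <= 0) {
    stop("sampling_rate must be a positive number (Hz)", call. = FALSE)
  }
  if (n > 1L) {
    steps <- diff(rec$time)
    if (any(steps <= 0)) {
      stop("time must be strictly increasing", call. = FALSE)
    }
    dev <- max(abs(steps - 1 / rec$sampling_rate))
    if (dev > .TIME_STEP_TOL) {
      stop("non-uniform time step: deviates from 1/sampling_rate by ",
           format(dev, digits = 3), " s (tolerance 1e-9 s)", call. = FALSE)
    }
  }
  if (rec$sampling_rate <= 2 * rec$frequency) {
    stop("sampling_rate (", rec$sampling_rate,
         " Hz) must exceed twice the perturbation frequency (",
         rec$frequency, " Hz)", call. = FALSE)
  }
  rec
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> ", x$subject_id, " ", x$visual_condition, " ",
      frequency_label(x$frequency), " trial ", x$trial_index, "\n", sep = "")
  cat("  ", length(x$time), " samples @ ", x$sampling_rate, " Hz (",
      format(trial_duration(x), digits = 4), " s), perturbation ",
      x$frequency, " Hz\n", sep = "")
  invisible(x)
}

#' Duration of a trial recording in seconds
#'
#' @param rec A `trial_recording`.
#' @return Length of the record in seconds (`n / sampling_rate`).
#' @export
trial_duration <- function(rec) {
  length(rec$time) / rec$sampling_rate
}

#' Label a platform translation frequency
#'
#' Maps the two protocol frequencies to their conventional labels:
#' 0.18 Hz -> `"LF"`, 0.56 Hz -> `"HF"`; anything else is formatted as
#' `"F<hz>Hz"`.
#'
#' @param frequency Frequency in Hz.
#' @return Character label.
#' @export
frequency_label <- function(frequency) {
  vapply(frequency, function(f) {
    if (isTRUE(all.equal(f, 0.18))) "LF"
    else if (isTRUE(all.equal(f, 0.56))) "HF"
    else sprintf("F%gHz", f)
  }, character(1))
}

#' Duration of one platform translation cycle
#'
#' One full period of the sinusoidal support-surface motion, `1/frequency`
#' seconds: 5.6 s at 0.18 Hz (LF) and 1.8 s at 0.56 Hz (HF). Used to express
#' time constants fitted in cycles in time units.
#'
#' @param frequency Platform translation frequency in Hz.
#' @return Cycle duration in seconds.
#' @export
cycle_duration <- function(frequency) {
  stopifnot(is.numeric(frequency), all(frequency > 0))
  1 / frequency
}

trace_of <- function(rec, segment = c("head", "pelvis", "platform")) {
  segment <- match.arg(segment)
  rec[[paste0(segment, "_ap")]]
}
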