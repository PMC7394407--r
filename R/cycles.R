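# Cycle segmentation. The platform trace is the clock of the protocol:
# perturbation onset is detected as the first departure from the quiet
# baseline, and cycle boundaries are the positive-going crossings of the
# post-onset midline (phase-unambiguous for a sinusoid), with a hysteresis
# band of 5% of the platform peak-to-peak amplitude to reject noise.

#' Detect perturbation onset from the platform trace
#'
#' Finds the first sample at which the platform departs from its quiet
#' baseline by more than `k` times the baseline SD (or `eps_floor` for
#' noiseless traces), then backtracks to the last sample still at baseline
#' level, so the reported onset is the start of the movement rather than
#' the threshold crossing.
#'
#' @param rec A [trial_recording()] with at least `baseline` seconds of
#'   still platform at the start.
#' @param k Threshold multiplier on the baseline SD.
#' @param baseline Length of the baseline window, s.
#' @param eps_floor Lower bound on the deviation threshold, cm; guards
#'   noiseless traces whose baseline SD is zero.
#' @return Onset sample index (1-based).
#' @export
detect_onset <- function(rec, k = 5, baseline = 1, eps_floor = 1e-6) {
  stopifnot(inherits(rec, "trial_recording"), k > 0, baseline > 0)
  x <- rec$platform_ap
  n_base <- floor(baseline * rec$sampling_rate)
  if (n_base < 2L || n_base >= length(x)) {
    stop("record too short for a ", baseline, " s baseline window",
         call. = FALSE)
  }
  base <- x[seq_len(n_base)]
  m <- mean(base)
  s <- max(sd(base), eps_floor)
  hit <- which(abs(x - m) > k * s)
  if (length(hit) == 0L) {
    stop("no perturbation detected: platform never deviates from baseline",
         call. = FALSE)
  }
  first <- hit[1]
  at_base <- which(abs(x[seq_len(first)] - m) <= s)
  if (length(at_base) == 0L) first else at_base[length(at_base)]
}

# forward-fill the nonzero entries of an integer state vector; leading
# zeros stay NA
locf_state <- function(s) {
  nz <- s != 0L
  cs <- cumsum(nz)
  out <- rep(NA_integer_, length(s))
  keep <- cs > 0L
  out[keep] <- s[nz][cs[keep]]
  out
}

#' Segment a recording into platform translation cycles
#'
#' Cycle boundaries are the onset sample followed by each positive-going
#' crossing of the platform trace through its post-onset midline (mean of
#' the post-onset platform trace, robust to baseline offset). A crossing is
#' registered when the trace reaches the midline after having been below
#' `midline - hysteresis * PP`. Windows are the half-open sample intervals
#' between successive boundaries; any trailing partial cycle is discarded.
#'
#' @param rec A [trial_recording()].
#' @param onset Onset sample from [detect_onset()].
#' @param frequency Platform translation frequency, Hz (defaults to the
#'   recording's metadata); used only for reporting expected window length.
#' @param hysteresis Hysteresis band as a fraction of the platform
#'   peak-to-peak amplitude.
#' @param max_cycles Keep only the first `max_cycles` windows (e.g. 27 to
#'   truncate an HF trial to the common analysis length); `NULL` keeps all.
#' @return A tibble of class `cycle_windows` with columns `cycle`,
#'   `start_sample`, `end_sample` (half-open), `start_time`, `end_time`.
#' @export
segment_cycles <- function(rec, onset, frequency = rec$frequency,
                           hysteresis = 0.05, max_cycles = NULL) {
  stopifnot(inherits(rec, "trial_recording"),
            onset >= 1, onset <= length(rec$platform_ap))
  x <- rec$platform_ap[onset:length(rec$platform_ap)]
  mid <- mean(x)
  h <- hysteresis * (max(x) - min(x))
  if (max(x) - min(x) <= 0) {
    stop("cannot segment: platform trace is constant after onset",
         call. = FALSE)
  }
  s <- integer(length(x))
  s[x >= mid] <- 1L
  s[x < mid - h] <- -1L
  state <- locf_state(s)
  up <- which(diff(state) == 2L) + 1L  # first sample at/above mid after arming
  boundaries <- c(1L, up[state[up] == 1L])
  boundaries <- sort(unique(boundaries))
  # the platform stops at the midline after the last cycle, so the final
  # cycle has no upward crossing behind it; close it from the nominal
  # period when a full period of samples remains past the last crossing
  period <- rec$sampling_rate / frequency
  tail_len <- length(x) - boundaries[length(boundaries)]
  if (tail_len >= period - 1) {
    boundaries <- c(boundaries,
                    min(boundaries[length(boundaries)] +
                          as.integer(round(period)),
                        length(x)))
  }
  if (length(boundaries) < 2L) {
    stop("cannot segment: fewer than 2 cycle boundaries found",
         call. = FALSE)
  }
  start <- boundaries[-length(boundaries)] + onset - 1L
  end <- boundaries[-1L] + onset - 1L
  win <- tibble(
    cycle = seq_along(start),
    start_sample = start,
    end_sample = end,
    start_time = rec$time[start],
    end_time = rec$time[end]
  )
  if (!is.null(max_cycles) && nrow(win) > max_cycles) {
    win <- win[seq_len(max_cycles), ]
  }
  attr(win, "frequency") <- frequency
  attr(win, "sampling_rate") <- rec$sampling_rate
  class(win) <- c("cycle_windows", class(win))
  win
}

#' Per-cycle peak-to-peak displacement and mean AP position
#'
#' For each cycle window, the peak-to-peak (PP) displacement is
#' `max - min` of the segment trace within the window and the mean AP
#' position is the within-window mean referenced to the first cycle (cycle
#' 1 maps to 0 exactly), so positions are expressed as shifts relative to
#' the start of the perturbation sequence.
#'
#' @param rec A [trial_recording()].
#' @param windows Cycle windows from [segment_cycles()] on the same
#'   recording.
#' @param segment One of `"head"`, `"pelvis"`, `"platform"`.
#' @param lowpass Optional low-pass cutoff in Hz applied to the trace
#'   (zero-phase 2nd-order Butterworth) before the metrics are taken.
#'   Default `NULL`: metrics are computed on the raw trace. Intended for
#'   noisy real recordings; note that wide-band noise inflates the
#'   peak-to-peak of a raw trace by the expected range of the noise over
#'   the window.
#' @return A tibble of class `cycle_series` with columns `segment`,
#'   `cycle`, `pp` (cm) and `mean_ap` (cm, cycle-1-referenced); attribute
#'   `"frequency"` carries the platform frequency.
#' @export
per_cycle_metrics <- function(rec, windows,
                              segment = c("head", "pelvis", "platform"),
                              lowpass = NULL) {
  segment <- match.arg(segment)
  stopifnot(inherits(rec, "trial_recording"), nrow(windows) >= 1)
  x <- trace_of(rec, segment)
  if (!is.null(lowpass)) {
    stopifnot(lowpass > 0, lowpass < rec$sampling_rate / 2)
    bf <- signal::butter(2, lowpass / (rec$sampling_rate / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  if (max(windows$end_sample) - 1L > length(x)) {
    stop("windows extend beyond the recording", call. = FALSE)
  }
  pp <- numeric(nrow(windows))
  raw_mean <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- windows$start_sample[i]:(windows$end_sample[i] - 1L)
    if (length(idx) == 0L) stop("empty cycle window ", i, call. = FALSE)
    w <- x[idx]
    pp[i] <- max(w) - min(w)
    raw_mean[i] <- mean(w)
  }
  out <- tibble(
    segment = segment,
    cycle = windows$cycle,
    pp = pp,
    mean_ap = raw_mean - raw_mean[1]
  )
  attr(out, "frequency") <- attr(windows, "frequency") %||% rec$frequency
  class(out) <- c("cycle_series", class(out))
  out
}

#' Segment and measure a recording in one call
#'
#' Convenience wrapper: [detect_onset()], [segment_cycles()] and
#' [per_cycle_metrics()] for the requested segments.
#'
#' @param rec A [trial_recording()].
#' @param segments Segments to measure.
#' @param max_cycles Passed to [segment_cycles()].
#' @param k Onset threshold multiplier, passed to [detect_onset()].
#' @param lowpass Optional low-pass cutoff in Hz, passed to
#'   [per_cycle_metrics()].
#' @return A list with `onset`, `windows` and one `cycle_series` per
#'   requested segment.
#' @export
analyze_cycles <- function(rec, segments = c("head", "pelvis"),
                           max_cycles = NULL, k = 5, lowpass = NULL) {
  onset <- detect_onset(rec, k = k)
  windows <- segment_cycles(rec, onset, max_cycles = max_cycles)
  series <- lapply(segments,
                   function(s) per_cycle_metrics(rec, windows, s,
                                                 lowpass = lowpass))
  names(series) <- segments
  c(list(onset = onset, windows = windows), series)
}
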