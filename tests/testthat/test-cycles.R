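test_that("onset is detected within 2 samples of the true 5 s pre-period", {
  rec <- generate_trial(protocol_cfg(noise_sd = 0))
  onset <- detect_onset(rec)
  expect_lt(abs(rec$time[onset] - 5.0), 2 / 140 + 1e-12)
})

test_that("onset detection fails on a still platform and ignores offsets", {
  cfg <- quick_cfg()
  rec <- generate_trial(cfg)
  still <- rec
  still$platform_ap <- rep(0, length(rec$time))
  expect_error(detect_onset(still), "no perturbation detected")

  shifted <- rec
  shifted$platform_ap <- rec$platform_ap + 3.7
  expect_identical(detect_onset(shifted), detect_onset(rec))
})

test_that("LF and HF protocol trials segment into the protocol cycle counts", {
  lf <- generate_trial(protocol_cfg(noise_sd = 0))
  a <- analyze_cycles(lf, segments = character(0))
  expect_identical(nrow(a$windows), 27L)
  # each LF window spans one period (1/0.18 = 5.56 s) within one sample
  lens <- a$windows$end_sample - a$windows$start_sample
  expect_true(all(abs(lens - 140 / 0.18) <= 1))

  hf <- generate_trial(protocol_cfg(frequency = 0.56, noise_sd = 0))
  b <- analyze_cycles(hf, segments = character(0))
  expect_identical(nrow(b$windows), 31L)
  lens <- b$windows$end_sample - b$windows$start_sample
  expect_true(all(abs(lens - 140 / 0.56) <= 1 + 1e-6))
})

test_that("segmentation count matches the generator across a frequency/rate grid", {
  for (f in c(0.1, 0.36, 1)) {
    for (fs in c(100, 140, 200)) {
      cfg <- synth_config(frequency = f, n_cycles = 5L, sampling_rate = fs,
                          pre_period = 2, post_period = 0.5, noise_sd = 0,
                          seed = 1)
      rec <- generate_trial(cfg)
      a <- analyze_cycles(rec, segments = character(0))
      expect_identical(nrow(a$windows), 5L,
                       label = sprintf("cycles at f=%g fs=%g", f, fs))
      # windows tile the record: sample-exact adjacency, no gaps
      expect_identical(a$windows$start_sample[-1],
                       a$windows$end_sample[-nrow(a$windows)])
    }
  }
})

test_that("a pure 5 cm amplitude sinusoid yields PP of 10 cm every cycle", {
  rec <- generate_platform(protocol_cfg(platform_pp = 10, noise_sd = 0))
  a <- analyze_cycles(rec, segments = "platform")
  expect_true(all(abs(a$platform$pp - 10) < 1e-3))
  expect_true(all(a$platform$pp >= 0))
})

test_that("constant trace gives zero PP and zero referenced position", {
  rec <- generate_trial(quick_cfg())
  win <- segment_cycles(rec, detect_onset(rec))
  rec$head_ap <- rep(4.2, length(rec$time))
  m <- per_cycle_metrics(rec, win, "head")
  expect_true(all(m$pp == 0))
  expect_true(all(m$mean_ap == 0))
})

test_that("PP is shift-invariant and mean position is cycle-1 referenced", {
  rec <- generate_trial(quick_cfg(noise_sd = 0.2, seed = 3))
  win <- segment_cycles(rec, detect_onset(rec))
  m0 <- per_cycle_metrics(rec, win, "head")
  expect_identical(m0$mean_ap[1], 0)

  shifted <- rec
  shifted$head_ap <- rec$head_ap + 11.3
  m1 <- per_cycle_metrics(shifted, win, "head")
  expect_equal(m1$pp, m0$pp)
  expect_equal(m1$mean_ap, m0$mean_ap)  # constant shift cancels after referencing
})

test_that("linear drift shows in mean position at d per cycle, PP untouched", {
  # 3-cycle toy at 1 Hz / 50 Hz: x = sin + drift of d cm per cycle,
  # with a 0.5 s still tail after the last cycle (as the platform protocol)
  fs <- 50; f <- 1; n_cyc <- 3; d <- 0.1
  time <- (0:(fs * (n_cyc + 1.5) - 1)) / fs
  tp <- time - 1  # 1 s pre-period
  plat <- ifelse(tp >= 0 & tp < n_cyc / f, 5 * sin(2 * pi * f * tp), 0)
  body <- plat + ifelse(tp >= 0, d * f * tp, 0)
  rec <- trial_recording(time, plat, body, body, sampling_rate = fs,
                         frequency = f)
  a <- analyze_cycles(rec, segments = "head")
  # brute-force expected window means from the same sample windows
  expected <- vapply(seq_len(nrow(a$windows)), function(i) {
    idx <- a$windows$start_sample[i]:(a$windows$end_sample[i] - 1)
    mean(body[idx])
  }, numeric(1))
  expect_equal(a$head$mean_ap, expected - expected[1], tolerance = 1e-12)
  # boundary jitter of +/-1 sample moves a window mean by ~d/period
  expect_equal(diff(a$head$mean_ap), rep(d, n_cyc - 1), tolerance = 0.03)
  expect_true(all(abs(a$head$pp - 10) < 0.2))
})

test_that("the low-pass option removes wide-band noise inflation of PP", {
  cfg <- protocol_cfg(noise_sd = 0.5, coordination = 1, seed = 8,
                      head = pp_envelope(A = 10, I = 10, tau = 1))
  rec <- generate_trial(cfg)
  a <- analyze_cycles(rec, segments = character(0))
  raw <- per_cycle_metrics(rec, a$windows, "head")
  smooth <- per_cycle_metrics(rec, a$windows, "head", lowpass = 3)
  expect_gt(mean(raw$pp), 12)        # range of the noise inflates raw PP
  expect_lt(abs(mean(smooth$pp) - 10), 0.5)
})

test_that("segmentation errors are informative", {
  rec <- generate_trial(quick_cfg())
  expect_error(segment_cycles(rec, onset = length(rec$time) - 3),
               "cannot segment")
})
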