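# discretization bound on the PP of a sampled sinusoid of amplitude a:
# each extremum can be missed by at most half a sample
pp_disc_bound <- function(a, f, fs) 2 * a * (1 - cos(pi * f / fs))

test_that("platform trace has protocol geometry: duration, amplitude, onset", {
  cfg <- protocol_cfg(noise_sd = 0)
  rec <- generate_platform(cfg)
  # post-onset perturbation lasts n_cycles / f = 27 / 0.18 = 150 s
  active <- which(rec$platform_ap != 0)
  expect_equal(rec$time[active[1]] - 5, 0, tolerance = 0.02)
  expect_gt(diff(range(rec$time[active])), 150 - 0.1)
  expect_lt(diff(range(rec$time[active])), 150 + 0.1)
  # positive-going onset from the midline
  expect_gt(rec$platform_ap[active[1]], 0)
})

test_that("measured per-cycle platform PP is 10 cm up to discretization", {
  cfg <- protocol_cfg(noise_sd = 0)
  rec <- generate_platform(cfg)
  a <- analyze_cycles(rec, segments = "platform")
  expect_identical(nrow(a$windows), 27L)
  bound <- pp_disc_bound(5, 0.18, 140) + 1e-9
  expect_true(all(abs(a$platform$pp - 10) <= bound + 1e-3))
})

test_that("HF config yields 31 segmentable cycles", {
  cfg <- protocol_cfg(frequency = 0.56, noise_sd = 0)
  rec <- generate_trial(cfg)
  a <- analyze_cycles(rec, segments = "platform")
  expect_identical(nrow(a$windows), 31L)
})

test_that("noiseless per-cycle PP follows the envelope G(n) for every cycle", {
  cfg <- protocol_cfg(noise_sd = 0, coordination = 1,
                      head = pp_envelope(A = 12, I = 8, tau = 3),
                      pelvis = pp_envelope(A = 9, I = 11, tau = 2))
  rec <- generate_trial(cfg)
  a <- analyze_cycles(rec, segments = c("head", "pelvis"))
  for (seg in c("head", "pelvis")) {
    env <- cfg[[seg]]
    g <- envelope_at(env, a[[seg]]$cycle)
    bound <- pp_disc_bound(max(g) / 2, cfg$frequency, cfg$sampling_rate)
    expect_true(all(abs(a[[seg]]$pp - g) <= bound + 1e-9),
                label = paste("envelope fidelity for", seg))
  }
  # head reaches within 1% of A by cycle 15 (3*tau = 9 < 15)
  expect_lt(abs(a$head$pp[15] - 12) / 12, 0.01)
})

test_that("identical config and seed give bit-identical trials", {
  cfg <- quick_cfg(noise_sd = 0.4, coordination = 0.8, seed = 123)
  r1 <- generate_trial(cfg)
  r2 <- generate_trial(cfg)
  expect_identical(r1$head_ap, r2$head_ap)
  expect_identical(r1$pelvis_ap, r2$pelvis_ap)
  # and the caller's RNG stream is untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(generate_trial(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("lambda = 1 with no noise gives per-cycle correlation exactly 1", {
  rec <- generate_trial(quick_cfg(coordination = 1, noise_sd = 0))
  a <- analyze_cycles(rec, segments = character(0))
  ccs <- cc_per_cycle(rec, a$windows)
  expect_true(all(abs(ccs$cc - 1) < 1e-12))
})

test_that("empirical per-cycle correlation converges to lambda (0.9) over seeds", {
  cfg <- quick_cfg(frequency = 0.56, n_cycles = 10L, sampling_rate = 140,
                   coordination = 0.9, noise_sd = 0)
  means <- vapply(1:100, function(s) {
    cfg$seed <- s
    rec <- generate_trial(cfg)
    a <- analyze_cycles(rec, segments = character(0))
    mean(cc_per_cycle(rec, a$windows)$cc)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.9), 0.02)
})

test_that("expected_cc accounts for measurement-noise attenuation", {
  cfg <- quick_cfg(frequency = 0.56, n_cycles = 10L, sampling_rate = 140,
                   coordination = 0.9, noise_sd = 1,
                   head = pp_envelope(10, 10, 1), pelvis = pp_envelope(10, 10, 1))
  expected <- expected_cc(cfg, n = 1)
  # analytic: lambda * s^2 / (s^2 + sigma^2), s = G/(2*sqrt(2))
  s2 <- (10 / (2 * sqrt(2)))^2
  expect_equal(expected, 0.9 * s2 / (s2 + 1), tolerance = 1e-12)
  means <- vapply(1:60, function(s) {
    cfg$seed <- s
    rec <- generate_trial(cfg)
    a <- analyze_cycles(rec, segments = character(0))
    mean(cc_per_cycle(rec, a$windows)$cc)
  }, numeric(1))
  expect_lt(abs(mean(means) - expected), 0.03)
})

test_that("invalid envelopes and coordination values are rejected", {
  expect_error(pp_envelope(A = -1, I = 8, tau = 2), "A, I and tau")
  expect_error(pp_envelope(A = 10, I = 0, tau = 2), "A, I and tau")
  expect_error(cc_course(A = 1.2), "A <= 1")
  expect_error(synth_config(frequency = 0.56, sampling_rate = 1),
               "twice the platform frequency")
})

test_that("cohort cardinality, determinism and zero-jitter degeneracy", {
  cfgs <- list(quick_cfg(visual_condition = "EO"),
               quick_cfg(visual_condition = "EC"))
  ch <- generate_cohort(cfgs, n_subjects = 2, n_trials = 2,
                        jitter_sd = 0.1, seed = 9)
  expect_length(ch$trials, 2 * 2 * 2)
  expect_identical(nrow(ch$truth), 2L * 2L * 2L)  # subjects x configs x segments

  ch2 <- generate_cohort(cfgs, n_subjects = 2, n_trials = 2,
                         jitter_sd = 0.1, seed = 9)
  expect_identical(ch$trials[[5]]$head_ap, ch2$trials[[5]]$head_ap)
  expect_identical(ch$truth, ch2$truth)

  flat <- generate_cohort(cfgs[1], n_subjects = 3, n_trials = 1,
                          jitter_sd = 0, seed = 4)
  expect_identical(flat$truth$A[flat$truth$segment == "head"],
                   rep(10, 3))
})

test_that("mean drift appears in per-cycle mean position, not in PP", {
  cfg <- quick_cfg(mean_drift = 2, noise_sd = 0)
  rec <- generate_trial(cfg)
  a <- analyze_cycles(rec, segments = "head")
  # linear ramp of 2 cm across 8 cycles: mean position climbs ~0.25 cm/cycle
  slope <- coef(lm(a$head$mean_ap ~ a$head$cycle))[2]
  expect_equal(unname(slope), 2 / 8, tolerance = 0.02)
  g <- envelope_at(cfg$head, a$head$cycle)
  expect_true(all(abs(a$head$pp - g) < 0.3))
})
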