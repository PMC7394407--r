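# Shared fixture builders. Everything is generated in code; trials used in
# fast unit tests are short (few cycles, modest sampling rate) unless the
# protocol geometry itself is under test.

# a short, cheap trial: 8 cycles at 0.5 Hz, 60 Hz sampling
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(frequency = 0.5, n_cycles = 8L, sampling_rate = 60,
                   pre_period = 2, post_period = 0.5,
                   head = pp_envelope(A = 10, I = 8, tau = 2),
                   pelvis = pp_envelope(A = 9, I = 7.5, tau = 1.5),
                   noise_sd = 0, coordination = 1, seed = 1)
  do.call(synth_config, modifyList(defaults, args))
}

# full-protocol LF trial (0.18 Hz, 27 cycles, 140 Hz, 5 s pre-period)
protocol_cfg <- function(...) {
  args <- list(...)
  do.call(synth_config, modifyList(list(seed = 1), args))
}

# noiseless per-cycle envelope series in the fitted parameterization
envelope_series <- function(A, I, tau, n = 27) {
  A + (I - A) * exp(-(seq_len(n) - 1) / tau)
}
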