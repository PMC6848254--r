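test_that("the simulated MEG signal is the weighted sink-plus-source sum", {
  cfg <- default_node_config(input = FALSE)
  r <- simulate_network(cfg, t_span = c(0, 1), dt = 5e-4, settle = 2)
  R <- meg_signal(r)
  direct <- 108 * r$mE[, 1] + 27 * r$mI[, 1]
  expect_equal(R, direct, tolerance = 1e-12)
  # all-zero rates give a zero signal
  cfg0 <- network_config(W_EE = matrix(0), W_IE = matrix(0),
                         W_EI = matrix(0), W_II = matrix(0),
                         W_EX = matrix(0), W_IX = matrix(0), B = 0,
                         sigmoid = sigmoid_params(e0 = 1e-300))
  r0 <- simulate_network(cfg0, t_span = c(0, 0.1), dt = 5e-4, settle = 0)
  expect_equal(max(abs(meg_signal(r0))), 0)
  # weight normalization is enforced
  expect_error(meg_weights(c(2)), "sum to 1")
  expect_error(meg_weights(c(-0.5, 1.5)), "non-negative")
})

test_that("peak detection finds constructed bumps and refuses monotone decay", {
  t <- seq(0, 2, by = 1e-3)
  bump <- exp(-((t - 1.12) / 0.05)^2)
  pk <- detect_osr_peak(t, bump, due_time = 1, search_window = 0.5)
  expect_true(pk$found)
  expect_equal(pk$latency, 0.12, tolerance = 2e-3)
  # invariant to adding a constant
  pk2 <- detect_osr_peak(t, bump + 100, 1, 0.5)
  expect_equal(pk2$latency, pk$latency)
  expect_equal(pk2$peak_amplitude, pk$peak_amplitude + 100)
  # monotone decay after the due time: no peak, not an error
  mono <- exp(-t)
  pk3 <- detect_osr_peak(t, mono, 1, 0.5)
  expect_false(pk3$found)
  expect_true(is.na(pk3$latency))
  # pre-due entrainment reference and secondary pre-peak flag
  sig <- bump + 0.5 * exp(-((t - 0.5) / 0.05)^2) +
    0.3 * exp(-((t - 1.05) / 0.01)^2)
  pk4 <- detect_osr_peak(t, sig, 1, 0.5)
  expect_equal(pk4$pre_due_peak_time, 0.5, tolerance = 5e-3)
  expect_true(pk4$has_pre_peak)
  expect_error(detect_osr_peak(t, bump, 1.9, 0.5), "window")
})

test_that("RMS envelope reproduces closed forms", {
  dt <- 1e-3
  expect_equal(rms_envelope(rep(3, 1000), 0.2, dt), rep(3, 1000))
  expect_equal(max(abs(rms_envelope(rep(0, 500), 0.1, dt))), 0)
  t <- seq(0, 5, by = dt)
  s <- sin(2 * pi * 10 * t)
  env <- rms_envelope(s, 0.1, dt)          # whole-period window
  mid <- env[t > 1 & t < 4]
  expect_equal(mean(mid), 1 / sqrt(2), tolerance = 1e-2)
  expect_error(rms_envelope(rep(1, 10), 1, dt), "exceeds")
})
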