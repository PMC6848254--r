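test_that("sigmoid is half-maximal at threshold, bounded and monotone", {
  expect_equal(sigmoid_rate(6), 2.5)
  expect_equal(sigmoid_rate(1e6), 5)
  expect_equal(sigmoid_rate(0), 5 / (1 + exp(0.56 * 6)))
  expect_equal(sigmoid_rate(0), 0.16785, tolerance = 1e-4)
  v <- seq(-40, 60, by = 0.25)
  m <- sigmoid_rate(v)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 5))
  p <- sigmoid_params(e0 = 4, r = 1, v0 = 0)
  expect_equal(sigmoid_rate(0, p), 4)
})

test_that("PSP kernel is gated, peaks at tau with height H/e, integrates to H*tau", {
  expect_equal(psp_kernel(0), 0)
  expect_equal(psp_kernel(-0.005), 0)
  expect_equal(psp_kernel(0.010), 3.25 / exp(1))
  expect_equal(psp_kernel(0.010), 1.195608, tolerance = 1e-5)
  t <- seq(0, 0.2, by = 1e-5)
  h <- psp_kernel(t)
  expect_equal(t[which.max(h)], 0.010, tolerance = 2e-5)
  expect_equal(stats::integrate(psp_kernel, 0, Inf)$value, 3.25 * 0.010,
               tolerance = 1e-7)
  pi_ <- synapse_params(H = 22, tau = 0.020)
  expect_equal(psp_kernel(0.020, pi_), 22 / exp(1))
})

test_that("kernel ODE pair has the stated rest, steady state and linearity", {
  expect_equal(kernel_ode_rhs(c(0, 0), 0), c(0, 0))
  # steady state under constant input: v* = H * tau * x
  st <- c(3.25 * 0.010 * 100, 0)
  expect_equal(kernel_ode_rhs(st, 100), c(0, 0), tolerance = 1e-12)
  # linearity: doubling input doubles the steady-state PSP
  st2 <- c(3.25 * 0.010 * 200, 0)
  expect_equal(kernel_ode_rhs(st2, 200), c(0, 0), tolerance = 1e-12)
})

test_that("integrating the ODE pair reproduces the kernel convolution", {
  # one decoupled excitatory pathway: x -> v through the kernel ODEs
  cfg <- network_config(W_EE = matrix(0), W_IE = matrix(0),
                        W_EI = matrix(0), W_II = matrix(0),
                        W_EX = matrix(1), W_IX = matrix(0), B = 0)
  dt <- 1e-4
  # bounded random piecewise-linear input on [0, 2]
  set.seed(7)
  knots <- seq(0, 2.2, by = 0.05)
  vals <- runif(length(knots), 0, 10)
  st <- new_stim <- NULL
  br <- data.frame(t = knots, v = vals)
  stim <- structure(list(channels = list(br),
                         meta = list(list(label = "noise", onsets = 0))),
                    class = "stimulus_set")
  res <- simulate_network(cfg, stim, t_span = c(0, 2), dt = dt, settle = 0)
  # oracle: trapezoidal discrete convolution with the finely sampled kernel
  step <- dt / 4
  tf <- seq(0, 2, by = step)
  xf <- as.vector(sample_stimuli(stim, tf))
  hf <- psp_kernel(tf)
  v_conv <- stats::convolve(xf, rev(hf), type = "open")[seq_along(tf)] * step
  v_conv <- v_conv - step / 2 * (xf[1] * hf)  # trapezoid ends (h(0) = 0)
  v_conv <- v_conv[seq(1, length(tf), by = 4)]
  err <- max(abs(res$vE[, 1] - v_conv)) / max(abs(v_conv))
  expect_lt(err, 1e-6)
})
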