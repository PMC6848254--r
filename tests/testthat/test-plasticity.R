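test_that("adaptation dynamics recover, decay and settle at the stated fixed point", {
  expect_equal(adaptation_rhs(1, 0), 0)
  expect_gt(adaptation_rhs(0.5, 0), 0)       # recovery toward 1
  # closed-form fixed point a* = 1 / (1 + tau_a * kappa * m)
  astar <- 1 / (1 + 0.2 * 2 * 2.5)
  expect_equal(astar, 0.5)
  expect_equal(adaptation_rhs(astar, 2.5), 0, tolerance = 1e-12)
  # boundary derivatives point inward
  expect_gte(adaptation_rhs(0, 10), 0)
  expect_lte(adaptation_rhs(1, 10), 0)
})

test_that("simulated efficacies stay in [0, 1] and spare external drive", {
  cfg <- default_node_config()
  r <- simulate_network(cfg, step_stimulus(0, 1.5), t_span = c(-0.5, 2.5),
                        dt = 5e-4, settle = 2,
                        adaptation = adaptation_params())
  expect_true(all(r$a_min >= 0 & r$a_min <= 1))
  expect_lt(min(r$a_min), 0.8)    # adaptation actually engaged
  # external weights untouched by adaptation
  expect_equal(r$config$W_EX[1, 1], 44)
})

test_that("trailing-window covariance matches its closed forms", {
  dt <- 1e-3
  t <- seq(0, 2, by = dt)
  expect_equal(windowed_covariance(rep(2, length(t)), rep(5, length(t)),
                                   0.5, 1.5, dt), 0)
  s <- sin(2 * pi * 5 * t)
  expect_equal(windowed_covariance(s, s, 0.4, 1.2, dt),
               stats::var(s[t > 0.8 & t <= 1.2 + dt / 2]), tolerance = 1e-6)
  # antiphase sinusoids over whole periods: cov = -amplitude^2 / 2
  a <- 1.7
  expect_equal(windowed_covariance(a * s, -a * s, 0.4, 1.2, dt),
               -a^2 / 2, tolerance = 1e-2)
  # window underflow at the start is defined as zero
  expect_equal(windowed_covariance(s, s, 0.4, 0.2, dt), 0)
  expect_error(windowed_covariance(s, s, 0.4, 3, dt), "beyond")
})

test_that("Gaussian index mask has unit peak and the stated width", {
  expect_equal(gaussian_mask(4, 4, 2), 1)
  expect_equal(gaussian_mask(6, 4, 2), exp(-0.5))
  expect_equal(gaussian_mask(6, 4, 2), 0.6065, tolerance = 1e-4)
  expect_lt(gaussian_mask(100, 1, 4), 1e-10)
  expect_error(gaussian_mask(1, 1, 0))
})

test_that("the plasticity rule strengthens excitation xor inhibition", {
  p <- stp_params(gain_scale = 1)           # raw rule
  # zero covariance: pure decay
  d <- stp_rhs(0.3, 0.2, 0, 1, 1, p)
  expect_equal(unname(d), c(-0.3, -0.2) / p$tau_w)
  # positive covariance: E-to-E fixed point at eta * c, E-to-I decays
  c0 <- 4
  expect_equal(unname(stp_rhs(p$eta * c0, 0, c0, 1, 1, p)), c(0, 0))
  # negative covariance: I-to-E fixed point at eta * beta * |c|
  beta <- 0.7
  expect_equal(unname(stp_rhs(0, p$eta * beta * c0, -c0, 1, beta, p)), c(0, 0))
  # never both targets positive for one pair
  for (cv in c(-3, -0.1, 0, 0.1, 3)) {
    d <- stp_rhs(0, 0, cv, 1, 1, p)
    expect_false(d[1] > 0 && d[2] > 0)
  }
})

test_that("covariance-driven plasticity binds in-phase pairs in simulation", {
  # two identical oscillating nodes share background drive and phase, so
  # their covariance is positive and mutual excitation grows while
  # cross-inhibition stays at zero
  cfg <- network_config(W_EE = diag(c(108, 108)), W_IE = diag(c(81, 81)),
                        W_EI = diag(c(27, 27)), W_II = diag(c(6.75, 6.75)),
                        W_EX = matrix(0, 2, 1), W_IX = matrix(0, 2, 1),
                        B = 550)
  r <- simulate_network(cfg, t_span = c(0, 2), dt = 5e-4, settle = 1,
                        stp = stp_params(N_b = 2, delta_t = 0.2),
                        stp_nodes = 1:2)
  expect_gt(r$WEE_final[1, 2], 1)
  expect_equal(r$WEI_final[1, 2], 0, tolerance = 1e-8)
  expect_gt(utils::tail(r$stp_wee_mean, 1), utils::head(r$stp_wee_mean, 1))
})
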