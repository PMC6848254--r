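test_that("standard configuration carries the canonical parameter values", {
  cfg <- default_node_config()
  expect_equal(cfg$W_EE[1, 1], 108)
  expect_equal(cfg$W_IE[1, 1], 81)
  expect_equal(cfg$W_EI[1, 1], 27)
  expect_equal(cfg$W_II[1, 1], 6.75)
  expect_equal(cfg$B, 550)
  expect_equal(cfg$W_IX[1, 1] / cfg$W_EX[1, 1], 0.5)
  expect_equal(cfg$H_e, 3.25); expect_equal(cfg$tau_e, 0.010)
  expect_equal(cfg$H_i, 22); expect_equal(cfg$tau_i, 0.020)
  expect_equal(cfg$sigmoid$e0, 2.5)
})

test_that("configuration validation rejects inconsistent input", {
  expect_error(network_config(W_EE = matrix(-1), W_IE = matrix(0),
                              W_EI = matrix(0), W_II = matrix(0)),
               "non-negative")
  expect_error(network_config(W_EE = matrix(0, 2, 2), W_IE = matrix(0),
                              W_EI = matrix(0, 2, 2), W_II = matrix(0, 2, 2)),
               "must be 2 x 2")
  expect_error(meg_weights(c(0.5, 0.6)), "sum to 1")
})

test_that("a fully decoupled silent node rests at the sigmoid of zero", {
  cfg <- network_config(W_EE = matrix(0), W_IE = matrix(0),
                        W_EI = matrix(0), W_II = matrix(0),
                        W_EX = matrix(0), W_IX = matrix(0), B = 0)
  r <- simulate_network(cfg, t_span = c(0, 0.5), dt = 5e-4, settle = 1)
  expect_equal(max(abs(r$vE)), 0)
  expect_equal(max(abs(r$mE - sigmoid_rate(0))), 0, tolerance = 1e-10)
})

test_that("without inter-node coupling the unstimulated node is unaffected", {
  cfg <- two_node_config()      # all inter-node weights zero
  r1 <- simulate_network(cfg, step_stimulus(0, 1), t_span = c(-0.2, 1.5),
                         dt = 5e-4, settle = 1)
  r0 <- simulate_network(cfg, NULL, t_span = c(-0.2, 1.5),
                         dt = 5e-4, settle = 1)
  expect_identical(r1$mE[, 2], r0$mE[, 2])
  expect_false(identical(r1$mE[, 1], r0$mE[, 1]))
})

test_that("identical inputs give bit-identical trajectories", {
  cfg <- default_node_config()
  a <- simulate_network(cfg, step_stimulus(0, 0.5), t_span = c(0, 1),
                        dt = 5e-4, settle = 1)
  b <- simulate_network(cfg, step_stimulus(0, 0.5), t_span = c(0, 1),
                        dt = 5e-4, settle = 1)
  expect_identical(a$mE, b$mE)
  expect_identical(a$vI, b$vI)
})

test_that("halving the step shrinks the error like a 4th-order method", {
  cfg <- default_node_config(input = FALSE)
  run <- function(dt) simulate_network(cfg, t_span = c(0, 0.3), dt = dt,
                                       settle = 0)$vE[, 1]
  v1 <- run(1e-3); v2 <- run(5e-4); v3 <- run(2.5e-4)
  e1 <- max(abs(v1 - v2[seq(1, length(v2), 2)]))
  e2 <- max(abs(v2 - v3[seq(1, length(v3), 2)]))
  expect_gt(e1 / e2, 8)   # 16 for a clean 4th-order scheme
})

test_that("the isolated node is quiescent at weak drive and oscillates at strong drive", {
  cfg <- default_node_config(input = FALSE)
  amp_at <- function(B) {
    cfg$B <- B
    r <- simulate_network(cfg, t_span = c(0, 2), dt = 5e-4, settle = 3)
    diff(range(r$mE[, 1]))
  }
  expect_lt(amp_at(100), 1e-3)
  expect_gt(amp_at(550), 2)
})

test_that("rates stay within sigmoid bounds along entire trajectories", {
  cfg <- two_node_config(w21 = c(27, 40.5, 13.5, 13.5), w12 = c(54, 27, 0, 13.5))
  r <- simulate_network(cfg, step_stimulus(0, 2), t_span = c(-0.5, 4),
                        dt = 5e-4, settle = 2)
  expect_true(all(r$mE > 0 & r$mE < 5))
  expect_true(all(r$mI > 0 & r$mI < 5))
})

test_that("the batched scan kernel matches individual simulations", {
  pts <- rbind(c(13.5, 27, 27, 0, 27, 27, 0, 0),
               c(0, 54, 27, 13.5, 13.5, 0, 0, 0))
  for (cond in c("I", "IV")) {
    sc <- run_scan(pts, cond)
    for (i in 1:2) {
      cfgA <- apply_condition(two_node_config(w21 = pts[i, 1:4],
                                              w12 = pts[i, 5:8]),
                              cond)
      r <- simulate_network(cfgA$config, step_stimulus(0, 2),
                            t_span = c(-0.5, 4), dt = 5e-4, settle = 2,
                            adaptation = cfgA$adaptation)
      mx <- window_maxima(r$time, r$mE[, 2])
      expect_equal(unname(sc$maxima[i, ]), unname(mx), tolerance = 1e-10)
    }
  }
})

test_that("phase portraits report orientation and degenerate fixed points", {
  cfg <- network_config(W_EE = matrix(0), W_IE = matrix(0),
                        W_EI = matrix(0), W_II = matrix(0),
                        W_EX = matrix(0), W_IX = matrix(0), B = 0)
  r <- simulate_network(cfg, t_span = c(0, 1), dt = 5e-4, settle = 1)
  pp <- phase_portrait(r, 1)
  expect_equal(pp$signed_area, 0, tolerance = 1e-9)
  expect_equal(pp$orientation, "degenerate")

  cfg2 <- default_node_config(input = FALSE)
  r2 <- simulate_network(cfg2, t_span = c(0, 2), dt = 5e-4, settle = 3)
  pp2 <- phase_portrait(r2, 1)
  expect_gt(abs(pp2$signed_area), 1)
  expect_error(phase_portrait(r2, 1, c(10, 11)), "empty")
})

test_that("a non-finite trajectory aborts with a located diagnostic", {
  # a step far beyond the stability limit of the explicit scheme makes the
  # linear kernel dynamics blow up to overflow
  cfg <- default_node_config(input = FALSE)
  expect_error(simulate_network(cfg, t_span = c(0, 100), dt = 0.5,
                                settle = 0),
               "non-finite state at node")
})
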