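test_that("bank construction enforces monotone resonance frequencies", {
  bank <- build_bank()
  expect_equal(bank$N_b, 21)
  expect_equal(bank$c_node, 22)
  expect_true(all(diff(bank$freqs) > 0))
  expect_equal(range(bank$freqs), c(5, 20))
  expect_equal(range(bank$periods), c(0.05, 0.2))
  # bank kernels slow down as the period grows (time-rescaled copies)
  expect_true(all(diff(bank$config$tau_e[1:21]) < 0))
  # degenerate frequency range (uniform time constants) is rejected
  expect_error(build_bank(freq_range = c(8, 8)))
})

test_that("an isolated bank node responds selectively at its resonance period", {
  cfg <- default_node_config()
  cfg$B <- 114
  amp_at <- function(soa) {
    st <- periodic_train(soa, 0.05, 15)
    due <- st$meta[[1]]$due_time
    r <- simulate_network(cfg, st, t_span = c(0, due), dt = 5e-4, settle = 2)
    m <- r$mE[r$time > due - 3 * soa, 1]
    diff(range(m))
  }
  res <- amp_at(0.153)       # measured damped period at B = 114
  far <- amp_at(0.250)
  expect_gt(res, 2 * far)
})

test_that("calibration helpers recover the known node frequencies", {
  expect_equal(reference_frequency(), 9.7, tolerance = 0.02)
  expect_equal(damped_period(), 0.153, tolerance = 0.02)
})

test_that("an omission trial detects a post-due burst with the right anchors", {
  bank <- build_bank()
  tr <- osr_trial(bank, 0.125, 10)
  expect_equal(tr$due, 9 * 0.125 + 0.125)
  expect_true(tr$peak$found)
  expect_gt(tr$peak$latency, 0.05)
  expect_lt(tr$peak$latency, 0.4)
  # CONST control: prolonged stimulus, offset response after its end
  cc <- osr_trial(bank, 0.125, 10, const = TRUE)
  expect_true(cc$peak$found)
})

test_that("short-term plasticity sustains the resonance past the due time", {
  bank <- build_bank()
  soa <- 0.150
  st <- periodic_train(soa, 0.05, 10)
  due <- st$meta[[1]]$due_time
  amp_at <- function(stp_on) {
    r <- simulate_network(bank$config, st, t_span = c(-0.2, due + 0.6),
                          dt = 5e-4, settle = 2,
                          stp = if (stp_on) bank$stp else NULL,
                          stp_nodes = if (stp_on) 1:21 else NULL,
                          adaptation = bank$adaptation,
                          adapt_mask = bank$adapt_mask)
    g <- rowMeans(r$mE[, 1:21])
    sel <- r$time >= due & r$time < due + 0.3
    f <- 1 / soa
    2 * abs(mean((g[sel] - mean(g[sel])) * exp(-2i * pi * f * r$time[sel])))
  }
  expect_gt(amp_at(TRUE), 2 * amp_at(FALSE))
})

test_that("the shipped ratio-table fixture matches its generator", {
  f <- system.file("extdata", "frf_ratios.csv", package = "devmass")
  expect_true(nzchar(f))
  expect_equal(utils::read.csv(f), frf_ratio_table(), tolerance = 1e-12)
})

test_that("the receptive-field simulation reproduces its anchor rows", {
  rt <- data.frame(tone = 1:3, ratio1 = c(1, 0, 0.4),
                   ratio2 = c(0, 0, 0.15))
  fr <- example2_frf(ratio_table = rt)
  expect_equal(dim(fr$values)[1], 3)
  # no input at all: the row stays at its (oscillating) baseline -- zero
  # mean shift and no extra excursion beyond the pre-stimulus range
  pre <- fr$time < 0
  during <- fr$time > 0.1 & fr$time < 0.5
  expect_lt(abs(mean(fr$values[2, ])), 0.3)
  expect_lt(max(fr$values[2, during]) - max(fr$values[2, pre]), 0.25)
  # surround-only input at full strength: suppression plus offset peak
  row1 <- fr$values[1, ]
  during <- fr$time > 0.1 & fr$time < 0.5
  post <- fr$time > 0.5 & fr$time < 0.8
  expect_lt(max(row1[during]), max(row1[post]) - 0.5)
  expect_error(example2_frf(ratio_table = data.frame(ratio1 = 2, ratio2 = 0)),
               "ratios")
})

test_that("the roving-sequence network reports its transition metrics", {
  z <- example4_mmn()
  m <- z$metrics
  expect_true(all(is.finite(unlist(m))))
  expect_gt(m$onset_prominence, 0)
  expect_gt(m$offset_prominence, 0)
  expect_length(z$events$reg_to_rand, 1)
  expect_length(z$events$rand_to_reg, 1)
})
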