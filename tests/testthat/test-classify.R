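test_that("window maxima are taken strictly inside each window", {
  t <- seq(-0.5, 4, by = 0.005)
  mx <- window_maxima(t, rep(2, length(t)))
  expect_equal(unname(mx), rep(2, 5))
  # a single spike raises only its own window
  tr <- rep(1, length(t)); tr[which.min(abs(t - 0.25))] <- 9
  mx <- window_maxima(t, tr)
  expect_equal(unname(mx["post_onset"]), 9)
  expect_equal(unname(mx[c("pre_onset", "pre_offset", "post_offset1",
                           "post_offset2")]), rep(1, 4))
  # sampled sinusoid never exceeds its amplitude
  s <- 2 + 1.3 * sin(2 * pi * 8 * t)
  mx <- window_maxima(t, s)
  expect_true(all(mx <= 3.3 + 1e-12))
  expect_true(all(mx >= 3.3 - 0.02))
  expect_error(window_maxima(t[t > 0], rep(1, sum(t > 0))), "cover")
})

test_that("flat, bistable and composed traces get the stated labels", {
  t <- seq(-0.5, 4, by = 0.005)
  # flat trace: all deltas zero; zero does not exceed the level threshold
  expect_equal(categorize(t, rep(2, length(t)))$type, "Dec-None")
  # pre/post baselines differing by 1 spikes/s: bistable, hence others
  bist <- ifelse(t < 1, 1, 2)
  expect_equal(categorize(t, bist)$type, "others")
  # stimulus level +1 over both baselines with an extra onset transient
  env <- make_envelope(inc = TRUE, on = TRUE)
  res <- categorize(env$time, env$trace)
  expect_equal(res$type, "Inc-On")
  expect_gt(res$metrics[["dm_stim"]], 0)
  expect_gt(res$metrics[["dm_on"]], 0.5)
  # non-finite traces are others
  bad <- rep(1, length(t)); bad[10] <- NaN
  expect_equal(categorize(t, bad)$type, "others")
})

test_that("the eight exemplar envelopes map to their eight labels", {
  envs <- eight_envelopes()
  for (lbl in names(envs))
    expect_equal(categorize(envs[[lbl]]$time, envs[[lbl]]$trace)$type, lbl,
                 label = lbl)
})

test_that("every finite trace gets exactly one label and labels are shift-invariant", {
  t <- seq(-0.5, 4, by = 0.01)
  set.seed(11)
  for (i in 1:25) {
    tr <- abs(stats::filter(rnorm(length(t)), rep(1 / 30, 30),
                            sides = 1))
    tr[is.na(tr)] <- 0
    res <- categorize(t, tr)
    expect_true(res$type %in% response_types())
    shifted <- categorize(t, tr + 7)
    expect_equal(shifted$type, res$type)
    expect_equal(shifted$metrics, res$metrics, tolerance = 1e-9)
  }
})

test_that("the standalone file classifier round-trips a trace", {
  env <- make_envelope(inc = FALSE, off = TRUE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = env$time, value = env$trace), f,
                   row.names = FALSE)
  res <- classify_trace_file(f)
  expect_equal(res$type, "Dec-Off")
  j <- classify_trace_file(f, json = TRUE)
  expect_match(as.character(j), "Dec-Off")
  expect_error(classify_trace_file(textConnection("a,b\n1,2")))
  unlink(f)
})
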