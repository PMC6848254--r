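test_that("grid enumeration is complete, ordered and on the 13.5 lattice", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 104976)
  expect_equal(ncol(g), 8)
  expect_equal(unname(g[1, ]), rep(0, 8))
  expect_true(all(abs(g / 13.5 - round(g / 13.5)) < 1e-9))
  expect_equal(sort(unique(g[, 1])), 135 * seq(0, 0.5, 0.1))
  expect_equal(sort(unique(g[, 3])), 135 * c(0, 0.1, 0.2))
  # deterministic lexicographic order: last column varies fastest
  expect_equal(unname(g[2, 8] - g[1, 8]), 13.5)
  expect_identical(g, enumerate_grid())
  g4 <- enumerate_grid("4d")
  expect_equal(nrow(g4), 324)
  expect_true(all(g4[, 5:8] == 0))
})

test_that("conditions transform the configuration as specified", {
  expect_equal(scan_condition("I")$f_EE, 1)
  expect_true(scan_condition("II")$zero_WIX)
  cIII <- scan_condition("III")
  expect_equal(cIII$f_EE, 0.75); expect_equal(cIII$f_IE, 0.5)
  expect_s3_class(scan_condition("IV")$adaptation, "adaptation_params")
  cfg <- two_node_config(w21 = c(13.5, 27, 0, 0))
  a <- apply_condition(cfg, "III")
  expect_equal(a$config$W_EE[1, 1], 108)          # intra untouched
  expect_equal(a$config$W_EE[2, 1], 13.5 * 0.75)  # inter reduced
  expect_equal(a$config$W_IE[2, 1], 27 * 0.5)
  b <- apply_condition(cfg, "II")
  expect_equal(max(b$config$W_IX), 0)
})

test_that("the decoupled grid point classifies as Dec-None, deterministically", {
  pt <- matrix(0, 1, 8)
  s1 <- run_scan(pt, "I")
  s2 <- run_scan(pt, "I")
  expect_equal(as.character(s1$labels), "Dec-None")
  expect_identical(s1$maxima, s2$maxima)
  expect_equal(s1$n_diverged, 0)
})

test_that("contingency tables are percentage partitions with consistent margins", {
  la <- factor(c("Inc-On", "Dec-None", "Dec-None", "others"), response_types())
  lb <- factor(c("Inc-On", "Dec-Off", "Dec-None", "others"), response_types())
  ct <- contingency(la, lb)
  expect_equal(sum(ct), 100)
  expect_equal(dim(ct), c(9, 9))
  expect_equal(unname(ct["Dec-None", "Dec-Off"]), 25)
  # identical labels concentrate on the diagonal
  ci <- contingency(la, la)
  expect_equal(sum(diag(ci)), 100)
  # margins equal the per-condition proportions
  expect_equal(unname(rowSums(ct)), unname(as.vector(type_proportions(la))))
  expect_error(contingency(la, lb[1:3]), "equal length")
  expect_equal(unname(onoff_counts(lb)), c(1, 1))
  expect_equal(unname(onoff_counts(c("Inc-OnOff", "Dec-Off"))), c(1, 2))
})

test_that("2-D embedding preserves row count and collocates duplicates", {
  set.seed(3)
  pts <- enumerate_grid()[sample(104976, 40), ]
  pts <- rbind(pts, pts[1, , drop = FALSE])    # duplicated point
  xy <- embed_2d(pts)
  expect_equal(dim(xy), c(41, 2))
  d <- sqrt(sum((xy[1, ] - xy[41, ])^2))
  expect_lt(d, 1e-8)
  expect_equal(dim(embed_2d(pts, "mds")), c(41, 2))
  expect_error(embed_2d(pts[0, ]), "empty")
})
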