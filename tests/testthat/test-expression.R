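test_that("compute_rpkm evaluates the formula and is linear", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(25, 500, 2e6), 25)  # 1e9*25/(2e6*500)
  expect_error(compute_rpkm(10, 0, 1e6), "length")
  expect_error(compute_rpkm(10, 100, 0), "total")
  expect_error(compute_rpkm(-1, 100, 1e6), "non-negative")

  set.seed(11)
  cnt <- sample(1:1000, 20)
  len <- sample(200:3000, 20)
  tot <- sample(1e5:1e7, 20)
  expect_equal(compute_rpkm(3 * cnt, len, tot), 3 * compute_rpkm(cnt, len, tot))
  expect_equal(compute_rpkm(cnt, 2 * len, tot), compute_rpkm(cnt, len, tot) / 2)
  expect_equal(compute_rpkm(cnt, len, 2 * tot), compute_rpkm(cnt, len, tot) / 2)
})

test_that("benjamini_hochberg matches the step-up rule and brute force", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(1.0), 1.0)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(21)
  for (rep in 1:30) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in sorted order
  }
})

test_that("call_differential gates on both fold change and FDR", {
  # identical counts in both conditions -> unchanged
  ct <- list(ids = c("a", "b"),
             control = matrix(c(100L, 50L, 100L, 50L), 2),
             treatment = matrix(c(100L, 50L, 100L, 50L), 2))
  len <- c(a = 500, b = 600)
  de <- call_differential(ct, len, total_control = 1e6, total_treatment = 1e6)
  expect_equal(de$direction, c("unchanged", "unchanged"))
  expect_equal(de$rpkm_control, de$rpkm_treatment)

  # fold ~3 but a test that returns large p-values -> unchanged
  ct2 <- list(ids = "a", control = matrix(100L), treatment = matrix(300L))
  de2 <- call_differential(ct2, c(a = 500), total_control = 1e6,
                           total_treatment = 1e6,
                           test_fun = function(c, t, nc, nt) rep(0.5, length(c)))
  expect_gt(de2$fold_change, 2)
  expect_equal(de2$direction, "unchanged")

  # strong planted change with ample counts -> called with tiny FDR
  ct3 <- list(ids = c("up", "flat"),
              control = matrix(c(200L, 200L, 210L, 190L), 2),
              treatment = matrix(c(800L, 200L, 790L, 205L), 2))
  de3 <- call_differential(ct3, c(up = 500, flat = 500),
                           total_control = 1e6, total_treatment = 1e6)
  expect_equal(de3$direction, c("up", "unchanged"))
  expect_lt(de3$fdr[1], 0.001)

  expect_error(call_differential(ct, c(a = 500)), "length")
})

test_that("pseudocounted fold change handles condition-specific transcripts", {
  ct <- list(ids = "only_treat", control = matrix(0L), treatment = matrix(400L))
  de <- call_differential(ct, c(only_treat = 400),
                          total_control = 1e6, total_treatment = 1e6)
  expect_true(is.finite(de$fold_change))
  expect_equal(de$direction, "up")
})
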