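# Survey validation statistics.

make_countmap <- function(cell_id, y) {
  structure(data.frame(cell_id = cell_id, stratum = "urban", y = y),
            class = c("count_map", "data.frame"))
}

test_that("exchangeable groups give a near-one p-value", {
  set.seed(1)
  cm <- make_countmap(0:19, runif(20, 0, 3))
  hh <- data.frame(household_id = 1:40, cell_id = rep(0:19, 2),
                   uses_pump = rep(c(TRUE, FALSE), each = 20))
  res <- compare_usage_groups(cm, hh, "pump")
  expect_gt(res$p_value, 0.9)
  expect_equal(res$n_using, 20)
})

test_that("a unit shift on a continuous map is detected with high power", {
  set.seed(2)
  cm <- make_countmap(0:399, c(runif(200, 1, 2), runif(200, 0, 1)))
  hh <- data.frame(household_id = 1:400, cell_id = 0:399,
                   uses_pump = rep(c(TRUE, FALSE), each = 200))
  res <- compare_usage_groups(cm, hh, "pump")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$mean_pred_using, res$mean_pred_not_using)
})

test_that("degenerate and empty groups are flagged untestable", {
  cm <- make_countmap(0:1, c(2, 2))
  hh_one_cell <- data.frame(household_id = 1:10, cell_id = 0,
                            uses_pump = rep(c(TRUE, FALSE), 5))
  expect_identical(compare_usage_groups(cm, hh_one_cell, "pump")$test_used,
                   "untestable")
  hh_empty <- data.frame(household_id = 1:4, cell_id = c(0, 0, 1, 1),
                         uses_pump = TRUE)
  expect_identical(compare_usage_groups(cm, hh_empty, "pump")$test_used,
                   "untestable")
})

test_that("the KS gate routes tied data to Wilcoxon and clean normal data to t", {
  set.seed(3)
  # heavily tied: households share few distinct cell predictions
  cm1 <- make_countmap(0:3, c(1, 2, 3, 4))
  hh1 <- data.frame(household_id = 1:80, cell_id = rep(0:3, 20),
                    uses_pump = rep(c(TRUE, FALSE), 40))
  expect_identical(compare_usage_groups(cm1, hh1, "pump")$test_used, "wilcoxon")
  # smooth normal predictions pass the KS gate
  cm2 <- make_countmap(0:399, rnorm(400, 5))
  hh2 <- data.frame(household_id = 1:400, cell_id = 0:399,
                    uses_pump = rep(c(TRUE, FALSE), each = 200))
  expect_identical(compare_usage_groups(cm2, hh2, "pump")$test_used, "t")
})

test_that("the pooled two-proportion z statistic matches the textbook formula", {
  expect_equal(two_proportion_ztest(8, 100, 8, 100)$z, 0)
  res <- two_proportion_ztest(12, 154, 11, 363)
  p1 <- 12 / 154; p2 <- 11 / 363; pool <- 23 / 517
  z_hand <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / 154 + 1 / 363))
  expect_equal(res$z, z_hand, tolerance = 1e-9)
  expect_equal(res$p_two_sided, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  expect_error(two_proportion_ztest(1, 10, 0, 0), ">= 1")
  expect_error(two_proportion_ztest(0, 10, 0, 20), "undefined")
})

test_that("the finite-population sample size formula behaves as documented", {
  res <- min_sample_size(3.841, 50000, 0.5, 0.05)
  # direct evaluation of the closed form
  raw_hand <- 3.841 * 50000 * 0.25 / (0.05^2 * 49999 + 3.841 * 0.25)
  expect_equal(res$raw, raw_hand, tolerance = 1e-12)
  expect_equal(res$ceiling, ceiling(raw_hand))
  # infinite-population limit bounds from above
  limit <- 3.841 * 0.25 / 0.05^2
  expect_lt(res$raw, limit)
  expect_equal(min_sample_size(3.841, 1e12, 0.5, 0.05)$raw, limit,
               tolerance = 1e-4)
  # monotone: larger tolerated error means fewer households
  s_d <- vapply(c(0.02, 0.05, 0.1), function(d)
    min_sample_size(3.841, 50000, 0.5, d)$raw, numeric(1))
  expect_true(all(diff(s_d) < 0))
  # monotone increasing in population size
  s_n <- vapply(c(1e3, 1e4, 1e5), function(n)
    min_sample_size(3.841, n, 0.5, 0.05)$raw, numeric(1))
  expect_true(all(diff(s_n) > 0))
})

test_that("group comparison is invariant to household order and unreferenced cells", {
  set.seed(6)
  cm <- make_countmap(0:49, runif(50, 0, 4))
  hh <- data.frame(household_id = 1:100, cell_id = rep(0:24, 4),
                   uses_pump = rep(c(TRUE, FALSE), 50))
  r1 <- compare_usage_groups(cm, hh, "pump")
  r2 <- compare_usage_groups(cm, hh[sample.int(100), ], "pump")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  cm_extra <- make_countmap(0:59, c(cm$y, runif(10)))
  r3 <- compare_usage_groups(cm_extra, hh, "pump")
  expect_equal(r1$p_value, r3$p_value)
})
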