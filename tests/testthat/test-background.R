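# Presence splitting, uniform and weighted background sampling, prior
# expectation.

test_that("the 70/30 split is record-level, sized by rounding, and seeded", {
  p <- presence_set("t", cells = 0:9)
  sp <- split_presences(p, 0.7, seed = 4)
  expect_equal(sp$train$n, 7L)
  expect_equal(sp$test$n, 3L)
  expect_setequal(c(sp$train$cells, sp$test$cells), 0:9)
  sp2 <- split_presences(p, 0.7, seed = 4)
  expect_identical(sp$train$cells, sp2$train$cells)
  # both partitions stay non-empty even at extreme fractions
  tiny <- split_presences(presence_set("t", 0:1), 0.999, seed = 1)
  expect_equal(c(tiny$train$n, tiny$test$n), c(1L, 1L))
  expect_error(split_presences(presence_set("t", 3L), 0.7), "at least 2")
})

test_that("duplicate records can straddle the split but cells cannot under by_cell", {
  p <- presence_set("t", cells = rep(0:4, each = 2))
  sp <- split_presences(p, 0.5, seed = 8, by_cell = TRUE)
  expect_length(intersect(unique(sp$train$cells), unique(sp$test$cells)), 0L)
})

test_that("uniform background excludes presence cells of all types and honours the ratio", {
  tab <- tiny_table()
  pres <- list(a = presence_set("a", c(0, 1, 2)), b = presence_set("b", c(3, 3)))
  bg <- sample_uniform_background(tab, pres, n_presence = 5, ratio = 4, seed = 2)
  expect_equal(bg$s, 20L)
  expect_length(intersect(bg$cells, c(0, 1, 2, 3)), 0L)
  expect_identical(bg$scheme, "uniform")
  # 100 presences at ratio 4 -> 400 cells (with-replacement fallback warns)
  expect_warning(
    bg2 <- sample_uniform_background(tab, pres, n_presence = 100, ratio = 4, seed = 2),
    "replacement")
  expect_equal(bg2$s, 400L)
  expect_length(intersect(bg2$cells, c(0, 1, 2, 3)), 0L)
  # half ratio
  expect_equal(sample_uniform_background(tab, pres, 20, ratio = 0.5,
                                         seed = 1)$s, 10L)
})

test_that("prior expectation distributes stratum totals by population", {
  tab <- tiny_table()
  tab$population <- c(1, 3, rep(0, 16), 2, 2, rep(0, 16))  # 2 urban + 2 rural carry all mass
  totals <- structure(data.frame(access_type = "a",
                                 stratum = c("urban", "rural"),
                                 y = c(100, 60)),
                      class = c("total_presences", "data.frame"))
  pr <- compute_prior_expectation(tab, totals, "a")
  expect_equal(pr$np[1:2], c(25, 75))
  expect_equal(sum(pr$np[tab$stratum == "urban"]), 100, tolerance = 1e-9)
  expect_equal(sum(pr$np[tab$stratum == "rural"]), 60, tolerance = 1e-9)
  # pooled variant normalizes over the whole population
  pr_pool <- compute_prior_expectation(tab, totals, "a", stratified = FALSE)
  expect_equal(pr_pool$np[1], 160 * 1 / 8)
})

test_that("inverse-expectation weights apply the zero-expectation max-weight rule", {
  w <- inverse_expectation_weights(c(25, 75, 0))
  expect_equal(w / sum(w), c(3, 1, 3) / 7)
  expect_error(inverse_expectation_weights(c(0, 0)), "all prior expectations")
})

test_that("weighted background draws avoid presence cells and favour low-expectation cells", {
  w <- default_world()
  tab <- default_table()
  pps_cells <- persons_per_point(tab, w$presences)
  pps <- do.call(rbind, lapply(w$config$access_types, function(t)
    average_persons_per_type(pps_cells, w$presences, t)))
  totals <- total_expected_presences(w$shares, tab, pps)
  pr <- compute_prior_expectation(tab, totals, "borehole")
  bg_w <- sample_weighted_background(pr, tab, w$presences, 100, ratio = 4, seed = 5)
  bg_u <- sample_uniform_background(tab, w$presences, 100, ratio = 4, seed = 5)
  used <- unique(unlist(lapply(w$presences, `[[`, "cells")))
  expect_length(intersect(bg_w$cells, used), 0L)
  expect_identical(bg_w$scheme, "weighted")
  # weighted sampling avoids the populated (high-expectation) cells
  popn <- function(cells) mean(tab$population[match(cells, tab$cell_id)])
  expect_lt(popn(bg_w$cells), popn(bg_u$cells))
  # determinism
  bg_w2 <- sample_weighted_background(pr, tab, w$presences, 100, ratio = 4, seed = 5)
  expect_identical(bg_w$cells, bg_w2$cells)
})

test_that("background sets never intersect recorded presences across many draws", {
  w <- small_world()
  tab <- world_cell_table(w)
  used <- unique(unlist(lapply(w$presences, `[[`, "cells")))
  for (s in 1:5) {
    bg <- sample_uniform_background(tab, w$presences, 40, ratio = 4, seed = s)
    expect_length(intersect(bg$cells, used), 0L)
  }
})
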