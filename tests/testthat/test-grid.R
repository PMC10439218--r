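# Cell lattice, resampling, collinearity screening, cell table.

test_that("cell ids are 0-based row-major with (0,0) at the north-west corner", {
  g <- grid_spec(3, 4)
  rc <- cell_rowcol(g, c(0, 3, 4, 11))
  expect_equal(rc$row, c(0, 0, 1, 2))
  expect_equal(rc$col, c(0, 3, 0, 3))
  expect_equal(rowcol_cell(g, rc$row, rc$col), c(0, 3, 4, 11))
  expect_error(grid_spec(0, 5), "positive")
  expect_error(grid_spec(2, 2, mask = c(TRUE, FALSE)), "mask")
})

test_that("bilinear resampling matches a direct four-corner oracle", {
  src <- grid_spec(2, 2)
  dst <- grid_spec(4, 4)
  lay <- feature_layer("f", "numerical", c(0, 2, 0, 2))
  out <- resample_layer(lay, src, dst)
  # oracle: evaluate the bilinear surface through the 4 src cell centres at
  # each dst centre, clamping coordinates to the border centres
  vals <- matrix(c(0, 2, 0, 2), 2, 2, byrow = TRUE)
  oracle <- sapply(0:15, function(id) {
    r <- id %/% 4; c <- id %% 4
    fr <- min(max((r + 0.5) / 2 - 0.5, 0), 1)
    fc <- min(max((c + 0.5) / 2 - 0.5, 0), 1)
    (1 - fr) * ((1 - fc) * vals[1, 1] + fc * vals[1, 2]) +
      fr * ((1 - fc) * vals[2, 1] + fc * vals[2, 2])
  })
  expect_equal(out$values, oracle, tolerance = 1e-12)
})

test_that("resampling a constant layer is constant and self-resampling is the identity", {
  src <- grid_spec(5, 7)
  const <- feature_layer("c", "numerical", rep(7, 35))
  expect_true(all(resample_layer(const, src, grid_spec(9, 11))$values == 7))
  set.seed(1)
  num <- feature_layer("n", "numerical", rnorm(35))
  expect_equal(resample_layer(num, src, src)$values, num$values, tolerance = 1e-12)
  cat_ <- feature_layer("k", "categorical", sample(0:2, 35, TRUE))
  expect_identical(resample_layer(cat_, src, src)$values, cat_$values)
})

test_that("nearest-neighbour resampling never invents categorical codes", {
  set.seed(3)
  src <- grid_spec(4, 4)
  lay <- feature_layer("k", "categorical", sample(c(1, 3, 9), 16, TRUE))
  up <- resample_layer(lay, src, grid_spec(10, 10))
  expect_true(all(up$values %in% lay$values))
  down <- resample_layer(lay, src, grid_spec(2, 3))
  expect_true(all(down$values %in% lay$values))
})

test_that("correlation screening computes the right statistics and drops one of each offending pair", {
  g <- grid_spec(1, 80)
  # categorical pair with joint table [[30,10],[10,30]] -> V = 0.5
  a <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  b <- rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  set.seed(9)
  x <- rnorm(80)
  st <- feature_stack(g, list(
    feature_layer("x", "numerical", x),
    feature_layer("x_copy", "numerical", x),
    feature_layer("ca", "categorical", a),
    feature_layer("cb", "categorical", b)))
  res <- correlation_screen(st, r_max = 0.7, v_max = 0.45, eta_max = 0.9)
  rep_ <- res$report
  pr <- rep_[rep_$layer_a == "x" & rep_$layer_b == "x_copy", ]
  expect_equal(pr$value, 1.0)
  expect_equal(pr$statistic_name, "pearson_r")
  cv <- rep_[rep_$statistic_name == "cramers_v" & rep_$layer_a == "ca", ]
  expect_equal(cv$value, 0.5, tolerance = 1e-12)
  # one of each offending pair dropped, survivors below thresholds
  nm <- names(res$stack$layers)
  expect_length(intersect(c("x", "x_copy"), nm), 1L)
  expect_length(intersect(c("ca", "cb"), nm), 1L)
  # idempotence: screening the survivors drops nothing
  res2 <- correlation_screen(res$stack, r_max = 0.7, v_max = 0.45, eta_max = 0.9)
  expect_identical(names(res2$stack$layers), nm)
})

test_that("independent layers are not dropped and constant layers are skipped with a warning", {
  set.seed(11)
  g <- grid_spec(100, 100)
  st <- feature_stack(g, list(
    feature_layer("u", "numerical", rnorm(10000)),
    feature_layer("v", "numerical", rnorm(10000))))
  res <- correlation_screen(st)
  expect_lt(abs(res$report$value), 0.05)
  expect_length(res$stack$layers, 2L)

  stc <- feature_stack(grid_spec(2, 5), list(
    feature_layer("flat", "numerical", rep(1, 10)),
    feature_layer("w", "numerical", rnorm(10))))
  expect_warning(correlation_screen(stc), "constant")
})

test_that("eta squared of a deterministic binning approaches one as bins refine", {
  set.seed(5)
  x <- rnorm(4000)
  e4 <- aquamap:::eta_squared_pair(x, cut(x, 4, labels = FALSE))
  e32 <- aquamap:::eta_squared_pair(x, cut(x, 32, labels = FALSE))
  expect_gt(e32, e4)
  expect_gt(e32, 0.99)
})

test_that("cell table one-hot encodes categoricals and validates inputs", {
  g <- grid_spec(2, 3)
  st <- feature_stack(g, list(
    feature_layer("n1", "numerical", 1:6),
    feature_layer("k1", "categorical", c(0, 1, 2, 0, 1, 2))))
  pop <- feature_layer("population", "numerical", rep(5, 6))
  strat <- feature_layer("stratum", "categorical", rep(0, 6))
  tab <- build_cell_table(st, pop, strat)
  expect_equal(ncol(feature_matrix(tab)), 4L)   # 1 numerical + 3 one-hot
  expect_true(all(tab$stratum == "urban"))
  expect_equal(rowSums(tab[, c("k1_0", "k1_1", "k1_2")]), rep(1, 6))

  empty <- grid_spec(2, 3, mask = rep(FALSE, 6))
  st2 <- feature_stack(empty, list(feature_layer("n1", "numerical", 1:6)))
  expect_error(build_cell_table(st2, pop, strat), "empty mask")
  bad_strat <- feature_layer("stratum", "categorical", rep(7, 6))
  expect_error(build_cell_table(st, pop, bad_strat), "stratum code")
})
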