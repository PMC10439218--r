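# Persons-per-source estimation, expected totals, count scaling.

test_that("per-cell persons per point divides population by the all-type point count", {
  tab <- tiny_table()
  tab$population[1:3] <- c(100, 0, 50)
  pres <- list(a = presence_set("a", c(0, 0, 1, 2)),
               b = presence_set("b", c(0, 0, 2)))
  s <- persons_per_point(tab, pres)
  expect_equal(s$s[s$cell_id == 0], 100 / 4)
  expect_equal(s$s[s$cell_id == 1], 0)        # recorded point, no people
  expect_equal(s$n_points[s$cell_id == 2], 2L)
  expect_false(5 %in% s$cell_id)              # no-point cells absent
})

test_that("per-type averages are stratified unweighted means over qualifying cells", {
  tab <- tiny_table()
  # three urban qualifying cells with s = 10, 20, 30 and one rural with s = 44
  tab$population[c(1, 2, 3, 19)] <- c(10, 20, 30, 44)
  pres <- list(a = presence_set("a", c(0, 1, 2, 18)),
               b = presence_set("b", integer(0)))
  s_cells <- persons_per_point(tab, pres)
  avg <- average_persons_per_type(s_cells, pres, "a")
  expect_equal(avg$s[avg$stratum == "urban"], 20)
  expect_equal(avg$s[avg$stratum == "rural"], 44)
  expect_equal(avg$n_cells_used, c(3L, 1L))
  # a type with no presences is undefined in both strata
  avg_b <- average_persons_per_type(s_cells, pres, "b")
  expect_true(all(is.na(avg_b$s)))
  expect_equal(avg_b$n_cells_used, c(0L, 0L))
})

test_that("expected totals follow share * stratum population / persons-per-source", {
  tab <- tiny_table()
  tab$population <- c(rep(10000 / 18, 18), rep(5000 / 18, 18))
  shares <- access_shares(data.frame(
    access_type = c("a", "a", "b", "b"),
    stratum = c("urban", "rural", "urban", "rural"),
    share = c(0.5, 0.2, 0, 0.3)))
  pps <- structure(data.frame(
    access_type = c("a", "a", "b", "b"),
    stratum = c("urban", "rural", "urban", "rural"),
    s = c(25, 50, NA, 10), n_cells_used = c(5L, 5L, 0L, 5L)),
    class = c("persons_per_source", "data.frame"))
  tot <- total_expected_presences(shares, tab, pps)
  expect_equal(tot$y[tot$access_type == "a" & tot$stratum == "urban"], 200)
  expect_equal(tot$y[tot$access_type == "a" & tot$stratum == "rural"], 20)
  # zero share -> zero total even with undefined s
  expect_equal(tot$y[tot$access_type == "b" & tot$stratum == "urban"], 0)
  # positive share with undefined s errors, naming the pair
  pps_bad <- pps; pps_bad$s[4] <- NA
  expect_error(total_expected_presences(shares, tab, pps_bad), "b, rural")
})

test_that("count scaling conserves stratum totals and is scale-invariant", {
  tab <- tiny_table()
  totals <- structure(data.frame(access_type = "a",
                                 stratum = c("urban", "rural"), y = c(50, 30)),
                      class = c("total_presences", "data.frame"))
  # uniform p* -> equal counts within stratum
  cm <- scale_to_counts(rep(0.4, 36), totals, tab, access_type = "a")
  expect_equal(cm$y[tab$stratum == "urban"], rep(50 / 18, 18))
  set.seed(4)
  p <- runif(36)
  cm1 <- scale_to_counts(p, totals, tab, access_type = "a")
  expect_equal(sum(cm1$y[cm1$stratum == "urban"]), 50, tolerance = 1e-9)
  expect_equal(sum(cm1$y[cm1$stratum == "rural"]), 30, tolerance = 1e-9)
  # doubling p* leaves counts unchanged
  cm2 <- scale_to_counts(2 * p, totals, tab, access_type = "a")
  expect_equal(cm1$y, cm2$y, tolerance = 1e-12)
  # monotone: higher p* means more counts within a stratum
  urb <- which(tab$stratum == "urban")
  expect_equal(order(cm1$y[urb]), order(p[urb]))
  # positive total with all-zero p* is an error
  p0 <- p; p0[tab$stratum == "urban"] <- 0
  expect_error(scale_to_counts(p0, totals, tab, access_type = "a"), "all-zero")
})

test_that("end-to-end counts recover the spatial pattern of true counts", {
  w <- default_world()
  tab <- default_table()
  X <- default_features()
  t <- "borehole"
  p <- w$presences[[t]]
  sp <- split_presences(p, 0.7, seed = 3)
  row_of <- function(cells) match(cells, tab$cell_id)
  bg <- sample_uniform_background(tab, w$presences, sp$train$n, ratio = 4, seed = 3)
  m <- suppressWarnings(fit_maxent(X[row_of(sp$train$cells), ], X[row_of(bg$cells), ],
                  basis = feature_basis(c("linear", "quadratic", "product")),
                  categorical_cols = categorical_columns(tab)))
  ps <- suppressWarnings(predict_scores(m, X))
  pps_cells <- persons_per_point(tab, w$presences)
  pps <- do.call(rbind, lapply(w$config$access_types, function(tt)
    average_persons_per_type(pps_cells, w$presences, tt)))
  totals <- total_expected_presences(w$shares, tab, pps)
  cm <- scale_to_counts(ps, totals, tab, access_type = t)
  truth <- w$true_counts[[t]][tab$cell_id + 1L]
  # Poisson thinning caps the attainable rank correlation: even the true
  # suitability surface only reaches the "oracle ceiling" against the
  # realized counts; the fitted map should recover at least half of it
  ceiling_rho <- cor(w$true_suitability[[t]][tab$cell_id + 1L], truth,
                     method = "spearman")
  rho <- cor(cm$y, truth, method = "spearman")
  expect_gt(rho, 0)
  expect_gt(rho, 0.5 * ceiling_rho)
  # conservation against the estimated totals
  for (st in c("urban", "rural"))
    expect_equal(sum(cm$y[cm$stratum == st]),
                 totals$y[totals$access_type == t & totals$stratum == st],
                 tolerance = 1e-6)
})
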