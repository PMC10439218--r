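# MLP classifier, hyperparameter search, permutation importance.

test_that("the MLP learns a linearly separable problem beyond chance", {
  set.seed(3)
  n <- 250
  Xp <- cbind(a = rnorm(n, 1.5), b = rnorm(n, 1.5))
  Xb <- cbind(a = rnorm(4 * n), b = rnorm(4 * n))
  m <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(10), activation = "relu",
                                max_iter = 300, batch_size = 64, seed = 0))
  Xp_te <- cbind(a = rnorm(100, 1.5), b = rnorm(100, 1.5))
  Xb_te <- cbind(a = rnorm(400), b = rnorm(400))
  ll <- log_loss(c(predict_scores(m, Xp_te), predict_scores(m, Xb_te)),
                 c(rep(1, 100), rep(0, 400)))
  chance <- -(0.2 * log(0.2) + 0.8 * log(0.8))
  expect_lt(ll, chance)
})

test_that("constant features drive predictions to the class prior", {
  X1 <- matrix(1, 50, 2, dimnames = list(NULL, c("a", "b")))
  X0 <- matrix(1, 150, 2, dimnames = list(NULL, c("a", "b")))
  m <- suppressWarnings(fit_mlp(X1, X0, hidden = c(5), activation = "logistic",
                                max_iter = 1500, batch_size = 32, seed = 1))
  expect_equal(mean(predict_scores(m, X1)), 0.25, tolerance = 0.05)
})

test_that("training is bit-reproducible under the seed", {
  set.seed(5)
  Xp <- cbind(a = rnorm(60, 1), b = rnorm(60))
  Xb <- cbind(a = rnorm(200), b = rnorm(200))
  m1 <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(8, 8), activation = "tanh",
                                 max_iter = 50, seed = 9))
  m2 <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(8, 8), activation = "tanh",
                                 max_iter = 50, seed = 9))
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  m3 <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(8, 8), activation = "tanh",
                                 max_iter = 50, seed = 10))
  expect_false(identical(m1$W, m3$W))
})

test_that("every activation and learning-rate schedule trains without error", {
  set.seed(7)
  Xp <- cbind(a = rnorm(40, 1)); Xb <- cbind(a = rnorm(120))
  for (act in c("identity", "logistic", "tanh", "relu"))
    for (sched in c("constant", "invscaling", "adaptive")) {
      m <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(4), activation = act,
                                    learning_rate = sched, max_iter = 30, seed = 2))
      p <- predict_scores(m, Xb)
      expect_true(all(p > 0 & p < 1))
    }
})

test_that("a single-configuration search returns it with one trial per fold", {
  set.seed(11)
  Xp <- cbind(a = rnorm(60, 1), b = rnorm(60))
  Xb <- cbind(a = rnorm(180), b = rnorm(180))
  space <- hyper_search_space(hidden_layer_sizes = list(c(5)),
                              activations = "relu",
                              learning_rate_schedules = "constant",
                              l1_ratio = 0, max_iter = 40,
                              n_trials = 1L, k_folds = 3L, batch_size = 32)
  res <- hyperparameter_search(space, Xp, Xb, seed = 4)
  expect_equal(nrow(res$report), 3L)
  expect_equal(res$best_config$hidden, c(5))
  # argmin property and seeded determinism on a 3-trial space
  space3 <- hyper_search_space(hidden_layer_sizes = list(c(3), c(6)),
                               activations = c("relu", "identity"),
                               learning_rate_schedules = "constant",
                               l1_ratio = 0, max_iter = 40,
                               n_trials = 3L, k_folds = 3L, batch_size = 32)
  r1 <- hyperparameter_search(space3, Xp, Xb, seed = 6)
  r2 <- hyperparameter_search(space3, Xp, Xb, seed = 6)
  expect_identical(r1$best_trial, r2$best_trial)
  expect_identical(r1$report$val_loss, r2$report$val_loss)
  expect_lte(min(r1$mean_cv_loss), stats::median(r1$mean_cv_loss))
})

test_that("fold-model selection uses the held-aside evaluation partition", {
  set.seed(13)
  Xp <- cbind(a = rnorm(60, 1)); Xb <- cbind(a = rnorm(180))
  Xp_ev <- cbind(a = rnorm(30, 1)); Xb_ev <- cbind(a = rnorm(90))
  space <- hyper_search_space(hidden_layer_sizes = list(c(4)),
                              activations = "relu",
                              learning_rate_schedules = "constant",
                              l1_ratio = 0, max_iter = 40,
                              n_trials = 1L, k_folds = 3L, batch_size = 32)
  res <- hyperparameter_search(space, Xp, Xb, seed = 8,
                               eval_presence = Xp_ev, eval_background = Xb_ev)
  expect_s3_class(res$model, "mlp_model")
})

test_that("permutation importance isolates informative features and ignores order", {
  set.seed(15)
  n <- 300
  Xp <- cbind(sig = rnorm(n, 1.2), noise = rnorm(n))
  Xb <- cbind(sig = rnorm(3 * n), noise = rnorm(3 * n))
  m <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(6), activation = "relu",
                                max_iter = 200, batch_size = 64, seed = 3))
  X <- rbind(Xp, Xb); y <- c(rep(1, n), rep(0, 3 * n))
  imp <- permutation_importance(m, X, y, n_repeats = 5, seed = 7)
  expect_gt(imp["sig"], 5 * max(imp["noise"], 1e-6))
  # column order invariance (same permutations reused for every group)
  imp_rev <- permutation_importance(m, X[, c("noise", "sig")], y,
                                    n_repeats = 5, seed = 7)
  expect_equal(imp[c("noise", "sig")], imp_rev, tolerance = 1e-12)
})

test_that("single-feature importance equals a direct two-pass recomputation", {
  set.seed(17)
  n <- 200
  Xp <- cbind(f = rnorm(n, 1)); Xb <- cbind(f = rnorm(2 * n))
  m <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(4), activation = "relu",
                                max_iter = 150, batch_size = 64, seed = 5))
  X <- rbind(Xp, Xb); y <- c(rep(1, n), rep(0, 2 * n))
  imp <- permutation_importance(m, X, y, n_repeats = 3, seed = 21)
  # oracle: replay the identical permutations by hand
  base <- log_loss(predict_scores(m, X), y)
  set.seed(21)
  perms <- lapply(1:3, function(i) sample.int(nrow(X)))
  deltas <- vapply(perms, function(pm) {
    Xs <- X; Xs[, "f"] <- X[pm, "f"]
    log_loss(predict_scores(m, Xs), y) - base
  }, numeric(1))
  expect_equal(unname(imp["f"]), mean(deltas) / base, tolerance = 1e-12)
})

test_that("mlp save/load round-trips predictions exactly", {
  set.seed(19)
  Xp <- cbind(a = rnorm(50, 1), b = rnorm(50))
  Xb <- cbind(a = rnorm(150), b = rnorm(150))
  m <- suppressWarnings(fit_mlp(Xp, Xb, hidden = c(6, 3), activation = "tanh",
                                max_iter = 60, seed = 11))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict_scores(m2, Xb), predict_scores(m, Xb), tolerance = 1e-12)
})
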