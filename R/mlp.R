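# Multi-layer perceptron presence/background classifier: logistic output
# unit, minibatch Adam on the log loss, elastic-net weight penalty.

activation_funs <- list(
  identity = list(f = function(x) x, df = function(a) array(1, dim(a))),
  logistic = list(f = function(x) 1 / (1 + exp(-x)), df = function(a) a * (1 - a)),
  tanh     = list(f = tanh, df = function(a) 1 - a^2),
  relu     = list(f = function(x) pmax(x, 0), df = function(a) (a > 0) * 1)
)

glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

mlp_forward <- function(W, b, act, X, keep_hidden = FALSE) {
  L <- length(W)
  H <- X
  hidden <- if (keep_hidden) vector("list", L - 1L) else NULL
  for (l in seq_len(L - 1L)) {
    H <- act$f(sweep(H %*% W[[l]], 2L, b[[l]], `+`))
    if (keep_hidden) hidden[[l]] <- H
  }
  p <- 1 / (1 + exp(-(drop(H %*% W[[L]]) + b[[L]])))
  list(p = p, hidden = hidden)
}

#' Fit an MLP presence/background classifier
#'
#' Labels are 1 for presence rows and 0 for background rows. The network
#' has the given hidden layer sizes, a shared hidden activation, and a
#' single logistic output unit whose value is interpreted as the relative
#' probability of presence. Training minimizes the log loss by minibatch
#' Adam, with an elastic-net penalty on the weights:
#' `alpha * (l1_ratio * sum|W| + (1 - l1_ratio) * 0.5 * sum W^2) / n`.
#' Inputs are standardized to zero mean / unit variance on the training
#' rows. Training stops early when the full-sample loss has not improved
#' by more than `tol` for `n_iter_no_change` consecutive epochs; reaching
#' `max_iter` without that triggers a non-convergence warning (the model is
#' still returned, with its final loss recorded). Fully reproducible under
#' `seed`.
#'
#' @param presence_features,background_features Numeric matrices with the
#'   same columns (>= 2 rows per class).
#' @param hidden Integer vector of hidden layer sizes, e.g. `c(50, 50)`.
#' @param activation One of `"identity"`, `"logistic"`, `"tanh"`, `"relu"`.
#' @param learning_rate Schedule: `"constant"`, `"invscaling"` (eta0 /
#'   epoch^0.5) or `"adaptive"` (divide by 5 after 2 epochs without
#'   improvement).
#' @param learning_rate_init Initial Adam step size.
#' @param alpha Penalty strength; `l1_ratio` mixes L1 (1) and L2 (0).
#' @param l1_ratio Elastic-net mixing weight in [0, 1].
#' @param max_iter Maximum epochs.
#' @param batch_size Minibatch size (clamped to n).
#' @param tol,n_iter_no_change Early-stopping rule.
#' @param seed Integer seed (weight init and batch shuffling).
#' @return Object of class `mlp_model`.
#' @export
fit_mlp <- function(presence_features, background_features,
                    hidden = c(10), activation = "relu",
                    learning_rate = "constant", learning_rate_init = 1e-3,
                    alpha = 1e-4, l1_ratio = 0,
                    max_iter = 500L, batch_size = 200L,
                    tol = 1e-4, n_iter_no_change = 10L, seed = 1) {
  Xp <- as.matrix(presence_features); Xb <- as.matrix(background_features)
  if (nrow(Xp) < 2L || nrow(Xb) < 2L) stop("need >= 2 rows per class")
  if (!identical(colnames(Xp), colnames(Xb)))
    stop("presence and background columns differ")
  act <- activation_funs[[match.arg(activation, names(activation_funs))]]
  learning_rate <- match.arg(learning_rate, c("constant", "invscaling", "adaptive"))

  X <- rbind(Xp, Xb)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd); scale_[scale_ == 0] <- 1
  X <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L

  set.seed(seed)
  W <- lapply(seq_len(L), function(l) glorot_init(sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0L
  lr <- learning_rate_init
  batch_size <- min(batch_size, n)

  full_loss <- function() {
    p <- mlp_forward(W, b, act, X)$p
    log_loss(p, y) + alpha * (l1_ratio * sum(abs(unlist(W))) +
      (1 - l1_ratio) * 0.5 * sum(unlist(W)^2)) / n
  }
  best <- Inf; stall <- 0L; adapt_stall <- 0L; converged <- FALSE
  n_epoch <- 0L

  for (epoch in seq_len(max_iter)) {
    n_epoch <- epoch
    if (learning_rate == "invscaling") lr <- learning_rate_init / sqrt(epoch)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + batch_size - 1L, n)]
      nb <- length(idx)
      Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
      fw <- mlp_forward(W, b, act, Xi, keep_hidden = TRUE)
      gW <- vector("list", L); gb <- vector("list", L)
      delta <- matrix((fw$p - yi) / nb, ncol = 1L)   # logistic + logloss
      for (l in L:1) {
        A_prev <- if (l == 1L) Xi else fw$hidden[[l - 1L]]
        gW[[l]] <- crossprod(A_prev, delta) +
          alpha * ((1 - l1_ratio) * W[[l]] + l1_ratio * sign(W[[l]])) / n
        gb[[l]] <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * act$df(fw$hidden[[l - 1L]])
      }
      tstep <- tstep + 1L
      corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    cur <- full_loss()
    if (cur < best - tol) { best <- cur; stall <- 0L; adapt_stall <- 0L }
    else { stall <- stall + 1L; adapt_stall <- adapt_stall + 1L }
    if (learning_rate == "adaptive" && adapt_stall >= 2L) {
      lr <- lr / 5; adapt_stall <- 0L
      if (lr <= 1e-6) { converged <- TRUE; break }
    }
    if (stall >= n_iter_no_change) { converged <- TRUE; break }
  }
  final <- full_loss()
  if (!converged)
    warning(sprintf("MLP reached max_iter = %d without convergence (final loss %.5f)",
                    max_iter, final))
  structure(list(W = W, b = b, layer_sizes = sizes, activation = activation,
                 center = center, scale = scale_,
                 hyper = list(hidden = hidden, activation = activation,
                              learning_rate = learning_rate,
                              learning_rate_init = learning_rate_init,
                              alpha = alpha, l1_ratio = l1_ratio,
                              max_iter = max_iter, batch_size = batch_size),
                 training_meta = list(seed = seed, iterations = n_epoch,
                                      final_loss = final, converged = converged)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> layers %s, %s activation, %d epochs, loss %.4f%s\n",
              paste(x$layer_sizes, collapse = "-"), x$activation,
              x$training_meta$iterations, x$training_meta$final_loss,
              if (x$training_meta$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
predict_scores.mlp_model <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(names(model$center)))
    X <- X[, names(model$center), drop = FALSE]   # align by name
  X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  act <- activation_funs[[model$activation]]
  mlp_forward(model$W, model$b, act, X)$p
}

#' Predict a relative-probability map from an MLP fit
#'
#' @inheritParams predict_maxent
#' @param model A [fit_mlp()] result.
#' @return A `suitability_map`.
#' @export
predict_mlp <- function(model, table = NULL, features = NULL,
                        access_type = "unknown", drop_layers = NULL) {
  X <- if (!is.null(features)) as.matrix(features)
       else feature_matrix(table, drop_layers)
  structure(list(access_type = access_type,
                 p_star = predict_scores(model, X),
                 cell_id = if (!is.null(table)) table$cell_id else NULL,
                 model_id = "mlp"),
            class = "suitability_map")
}

#' Define a random-search space for MLP hyperparameters
#'
#' Defaults reproduce the classifier grid commonly used with sklearn-style
#' MLPs: 22 single/double hidden layer widths from 5 to 100, four
#' activations, Adam with three learning-rate schedules, L1-ratio 0 or 1,
#' and three epoch budgets; 200 random draws scored by 5-fold CV.
#'
#' @param hidden_layer_sizes List of integer vectors.
#' @param activations,learning_rate_schedules,l1_ratio,max_iter Candidate
#'   sets.
#' @param n_trials Number of uniformly sampled configurations.
#' @param k_folds Cross-validation folds (>= 2).
#' @param alpha,learning_rate_init,batch_size Fixed training settings.
#' @return Object of class `hyper_search_space`.
#' @export
hyper_search_space <- function(
    hidden_layer_sizes = c(lapply(c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100), function(k) c(k)),
                           lapply(c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100), function(k) c(k, k))),
    activations = c("identity", "logistic", "tanh", "relu"),
    learning_rate_schedules = c("constant", "invscaling", "adaptive"),
    l1_ratio = c(0, 1),
    max_iter = c(500, 1000, 2500),
    n_trials = 200L, k_folds = 5L,
    alpha = 1e-4, learning_rate_init = 1e-3, batch_size = 200L) {
  stopifnot(length(hidden_layer_sizes) >= 1, length(activations) >= 1,
            length(learning_rate_schedules) >= 1, length(l1_ratio) >= 1,
            length(max_iter) >= 1, k_folds >= 2L)
  structure(list(hidden_layer_sizes = hidden_layer_sizes,
                 activations = activations,
                 learning_rate_schedules = learning_rate_schedules,
                 l1_ratio = l1_ratio, max_iter = max_iter,
                 n_trials = as.integer(n_trials), k_folds = as.integer(k_folds),
                 alpha = alpha, learning_rate_init = learning_rate_init,
                 batch_size = as.integer(batch_size)),
            class = "hyper_search_space")
}

stratified_folds <- function(n1, n0, k, seed) {
  if (min(n1, n0) < k)
    stop("too few rows in a class for ", k, "-fold stratified splitting")
  set.seed(seed)
  f1 <- sample(rep(seq_len(k), length.out = n1))
  f0 <- sample(rep(seq_len(k), length.out = n0))
  c(f1, f0)   # presence rows first, matching rbind order
}

#' Random hyperparameter search with stratified k-fold CV
#'
#' Samples `n_trials` configurations uniformly from the space; scores each
#' by mean validation log loss over stratified k-fold CV on the training
#' rows; picks the configuration with the lowest mean CV loss (first trial
#' wins ties). When the held-aside evaluation partition is supplied, the k
#' fold-models of the winning configuration are scored on it and the best
#' one is returned; otherwise the winner is refit on all training rows.
#'
#' @param space A [hyper_search_space()].
#' @param presence_features,background_features Training rows.
#' @param seed Integer seed fixing the trial sequence, folds and fits.
#' @param eval_presence,eval_background Optional held-aside evaluation rows.
#' @return List with `model`, `best_config`, and `report` (one row per
#'   trial x fold: trial id, config descriptor, fold, validation loss).
#' @export
hyperparameter_search <- function(space, presence_features, background_features,
                                  seed = 1, eval_presence = NULL,
                                  eval_background = NULL) {
  stopifnot(inherits(space, "hyper_search_space"))
  Xp <- as.matrix(presence_features); Xb <- as.matrix(background_features)
  k <- space$k_folds
  folds <- stratified_folds(nrow(Xp), nrow(Xb), k, seed)
  X <- rbind(Xp, Xb)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))

  set.seed(seed)
  trials <- lapply(seq_len(space$n_trials), function(i) list(
    hidden = space$hidden_layer_sizes[[sample.int(length(space$hidden_layer_sizes), 1)]],
    activation = space$activations[sample.int(length(space$activations), 1)],
    learning_rate = space$learning_rate_schedules[sample.int(length(space$learning_rate_schedules), 1)],
    l1_ratio = space$l1_ratio[sample.int(length(space$l1_ratio), 1)],
    max_iter = space$max_iter[sample.int(length(space$max_iter), 1)]
  ))

  fit_cfg <- function(cfg, Xp_tr, Xb_tr, fit_seed)
    suppressWarnings(fit_mlp(Xp_tr, Xb_tr, hidden = cfg$hidden,
            activation = cfg$activation, learning_rate = cfg$learning_rate,
            learning_rate_init = space$learning_rate_init, alpha = space$alpha,
            l1_ratio = cfg$l1_ratio, max_iter = cfg$max_iter,
            batch_size = space$batch_size, seed = fit_seed))

  cfg_label <- function(cfg) sprintf("h=(%s) act=%s lr=%s l1=%g it=%d",
    paste(cfg$hidden, collapse = ","), cfg$activation, cfg$learning_rate,
    cfg$l1_ratio, cfg$max_iter)

  rows <- list(); mean_loss <- numeric(space$n_trials)
  fold_models <- vector("list", space$n_trials)
  for (i in seq_along(trials)) {
    cfg <- trials[[i]]
    losses <- numeric(k); fms <- vector("list", k)
    for (fd in seq_len(k)) {
      tr <- folds != fd
      m <- fit_cfg(cfg, X[tr & y == 1, , drop = FALSE],
                   X[tr & y == 0, , drop = FALSE],
                   fit_seed = (seed + 131L * i + fd) %% .Machine$integer.max)
      p <- predict_scores(m, X[!tr, , drop = FALSE])
      losses[fd] <- log_loss(p, y[!tr])
      fms[[fd]] <- m
    }
    mean_loss[i] <- mean(losses)
    fold_models[[i]] <- fms
    rows[[i]] <- data.frame(trial = i, config = cfg_label(cfg),
                            fold = seq_len(k), val_loss = losses)
  }
  best_i <- which.min(mean_loss)   # first minimum wins ties
  best_cfg <- trials[[best_i]]
  if (!is.null(eval_presence) && !is.null(eval_background)) {
    Xe <- rbind(as.matrix(eval_presence), as.matrix(eval_background))
    ye <- c(rep(1, nrow(as.matrix(eval_presence))),
            rep(0, nrow(as.matrix(eval_background))))
    ev <- vapply(fold_models[[best_i]], function(m)
      log_loss(predict_scores(m, Xe), ye), numeric(1))
    model <- fold_models[[best_i]][[which.min(ev)]]
  } else {
    model <- fit_cfg(best_cfg, Xp, Xb,
                     fit_seed = (seed + 977L * best_i) %% .Machine$integer.max)
  }
  list(model = model, best_config = best_cfg,
       report = do.call(rbind, rows),
       mean_cv_loss = mean_loss, best_trial = best_i)
}

#' Permutation feature importance as relative loss contribution
#'
#' For each feature (or feature group: all one-hot columns of a categorical
#' layer are shuffled jointly), the increase in log loss when the feature's
#' values are randomly permuted, averaged over `n_repeats` permutations and
#' divided by the unpermuted total log loss. The same `n_repeats`
#' permutations are reused for every group, making the result invariant to
#' feature column order. If the base loss is zero the contributions are
#' returned unnormalized with a warning.
#'
#' @param model A fitted model with a [predict_scores()] method.
#' @param features Feature matrix used for scoring.
#' @param labels Binary labels.
#' @param n_repeats Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param groups Optional named list mapping group names to column names;
#'   default one group per column.
#' @return Named numeric vector of relative contributions.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 5,
                                   seed = 1, groups = NULL) {
  X <- as.matrix(features)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (is.null(groups))
    groups <- stats::setNames(as.list(colnames(X)), colnames(X))
  base <- log_loss(predict_scores(model, X), labels)
  set.seed(seed)
  perms <- lapply(seq_len(n_repeats), function(i) sample.int(nrow(X)))
  out <- vapply(groups, function(cols) {
    mean(vapply(perms, function(pm) {
      Xp <- X
      Xp[, cols] <- X[pm, cols, drop = FALSE]
      log_loss(predict_scores(model, Xp), labels) - base
    }, numeric(1)))
  }, numeric(1))
  if (base == 0) {
    warning("zero total loss (perfect fit); contributions returned unnormalized")
    return(out)
  }
  out / base
}

#' Column groups per source feature layer
#'
#' @param table A `cell_table`.
#' @param drop_layers Layers excluded from the model.
#' @return Named list of column-name vectors, one per source layer.
#' @export
feature_groups <- function(table, drop_layers = NULL) {
  info <- attr(table, "feature_info")
  info <- info[!(info$layer %in% drop_layers), , drop = FALSE]
  split(info$column, info$layer)
}
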