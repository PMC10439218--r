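# Threshold-based TPR/FPR, rank-based AUC, and the background-ratio
# sensitivity sweep contrasting them.

#' True positive rate at a threshold
#'
#' Fraction of test-presence scores strictly greater than `theta` (ties at
#' the threshold count as non-presence).
#'
#' @param scores Relative-probability scores on test presence cells.
#' @param theta Threshold in (0, 1); default 0.3.
#' @return TPR in [0, 1].
#' @export
tpr <- function(scores, theta = 0.3) {
  if (!length(scores)) stop("empty score list")
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  mean(scores > theta)
}

#' False positive rate at a threshold
#'
#' Fraction of background scores strictly greater than `theta`. Because
#' background cells may hold undetected presences, the best achievable FPR
#' in the presence-only setting can exceed zero.
#'
#' @param scores Scores on background cells.
#' @inheritParams tpr
#' @return FPR in [0, 1].
#' @export
fpr <- function(scores, theta = 0.3) {
  if (!length(scores)) stop("empty score list")
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  mean(scores > theta)
}

#' Rank-based AUC
#'
#' Probability that a random presence outscores a random background cell,
#' ties counted one half (the Mann-Whitney statistic scaled to [0, 1]).
#'
#' @param presence_scores,background_scores Non-empty score vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  n <- length(presence_scores); s <- length(background_scores)
  if (!n || !s) stop("empty score list")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * s)
}

#' Evaluation report for one model on one access type
#'
#' @param presence_scores Scores on the held-out test presences.
#' @param background_scores Scores on the evaluation background cells.
#' @param theta Presence threshold (default 0.3).
#' @param access_type,model_id Labels.
#' @return Object of class `eval_report` with `tpr`, `fpr`, `auc`, `n`, `s`.
#' @export
eval_report <- function(presence_scores, background_scores, theta = 0.3,
                        access_type = "unknown", model_id = "unknown") {
  structure(list(access_type = access_type, model_id = model_id,
                 theta = theta,
                 tpr = tpr(presence_scores, theta),
                 fpr = fpr(background_scores, theta),
                 auc = auc(presence_scores, background_scores),
                 n = length(presence_scores), s = length(background_scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s/%s: TPR %.3f, FPR %.3f, AUC %.3f (n=%d, s=%d, theta=%.2g)\n",
              x$access_type, x$model_id, x$tpr, x$fpr, x$auc, x$n, x$s, x$theta))
  invisible(x)
}

#' Background-ratio sensitivity sweep
#'
#' Holds the 70/30 presence split fixed, then for each background-to-
#' presence ratio re-samples the training background, re-trains the model
#' and evaluates TPR/FPR at `theta` and AUC on the fixed test presences
#' plus a freshly sampled evaluation background of fixed size
#' (`eval_ratio` times the test presence count, identical across ratios so
#' the rows are comparable). The sweep exposes the trade-off that a small
#' training ratio inflates both TPR and FPR while a large one deflates
#' them, with AUC nearly unchanged.
#'
#' @param trainer Function `(presence_features, background_features, seed)`
#'   returning a model with a [predict_scores()] method; see
#'   [mlp_trainer()] / [maxent_trainer()].
#' @param world A [generate_world()] result.
#' @param access_type Access type to sweep.
#' @param ratios Training background ratios (default 0.5, 2, 4, 8, 20).
#' @param seed Integer seed driving the split and all samples.
#' @param theta Presence threshold.
#' @param train_fraction Presence split fraction (default 0.7).
#' @param eval_ratio Evaluation background size as a multiple of the test
#'   presence count (default 4).
#' @return data.frame of class `sensitivity_table`: one row per ratio with
#'   `tpr`, `fpr`, `auc`, `n_train`, `s_train`.
#' @export
sensitivity_sweep <- function(trainer, world, access_type,
                              ratios = c(0.5, 2, 4, 8, 20), seed = 1,
                              theta = 0.3, train_fraction = 0.7,
                              eval_ratio = 4) {
  table <- world_cell_table(world)
  X <- cbind(feature_matrix(table), population = table$population)
  p <- world$presences[[access_type]]
  if (is.null(p) || p$n < 2L) stop("world has too few presences for ", access_type)
  sp <- split_presences(p, train_fraction, seed = seed)
  row_of <- function(cells) match(cells, table$cell_id)
  Xp_tr <- X[row_of(sp$train$cells), , drop = FALSE]
  Xp_te <- X[row_of(sp$test$cells), , drop = FALSE]
  n_test <- nrow(Xp_te)

  rows <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    bg_tr <- sample_uniform_background(table, world$presences, sp$train$n,
                                       ratio = r, seed = seed + 100 + i,
                                       access_type = access_type)
    model <- trainer(Xp_tr, X[row_of(bg_tr$cells), , drop = FALSE],
                     seed = seed + 200 + i)
    bg_ev <- sample_uniform_background(table, world$presences,
                                       round(eval_ratio * n_test), ratio = 1,
                                       seed = seed + 300 + i,
                                       access_type = access_type)
    sc_p <- predict_scores(model, Xp_te)
    sc_b <- predict_scores(model, X[row_of(bg_ev$cells), , drop = FALSE])
    data.frame(ratio = r, tpr = tpr(sc_p, theta), fpr = fpr(sc_b, theta),
               auc = auc(sc_p, sc_b), n_train = sp$train$n, s_train = bg_tr$s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Model trainer closures for sweeps and pipelines
#'
#' Thin wrappers binding training settings, so sweeps can re-train the same
#' configuration on varying data.
#'
#' @param ... Arguments passed to [fit_mlp()] / [fit_maxent()] (besides the
#'   data and seed).
#' @return A function `(presence_features, background_features, seed)`.
#' @export
mlp_trainer <- function(...) {
  args <- list(...)
  function(Xp, Xb, seed) {
    do.call(fit_mlp, c(list(presence_features = Xp, background_features = Xb,
                            seed = seed), args))
  }
}

#' @rdname mlp_trainer
#' @export
maxent_trainer <- function(...) {
  args <- list(...)
  function(Xp, Xb, seed) {
    do.call(fit_maxent, c(list(presence_features = Xp,
                               background_features = Xb), args))
  }
}

#' Build the model-ready cell table of a world
#'
#' @param world A [generate_world()] result.
#' @return A `cell_table` over the world's feature stack, population and
#'   strata.
#' @export
world_cell_table <- function(world) {
  build_cell_table(world$stack, world$population, world$strata)
}
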