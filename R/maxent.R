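# Maximum-entropy (Gibbs) presence/background model: L1-penalized
# exponential tilt of the background feature density, fitted by proximal
# gradient ascent with soft-thresholding.

#' Describe a MaxEnt feature basis
#'
#' The basis classes available to the Gibbs model: `linear` (the min-max
#' scaled feature itself), `quadratic` (its square), `product` (pairwise
#' products, i.e. bilinear terms), `hinge` (`max(0, z - t) / (1 - t)` at
#' each knot t), `threshold` (`1[z > t]`), and `categorical` (one-hot
#' indicator passthrough). Hinge and threshold knots sit at
#' `j / (knots + 1)`, j = 1..knots, on the scaled [0, 1] axis.
#'
#' @param classes Subset of the six class names; at least one.
#' @param hinge_knots,threshold_knots Knots per feature (>= 1 when the
#'   class is enabled).
#' @return Object of class `feature_basis`.
#' @export
feature_basis <- function(classes = c("linear", "quadratic", "product",
                                      "hinge", "threshold", "categorical"),
                          hinge_knots = 4, threshold_knots = 4) {
  all_classes <- c("linear", "quadratic", "product", "hinge", "threshold",
                   "categorical")
  classes <- match.arg(classes, all_classes, several.ok = TRUE)
  if (!length(classes)) stop("at least one basis class required")
  if ("hinge" %in% classes && hinge_knots < 1) stop("hinge_knots must be >= 1")
  if ("threshold" %in% classes && threshold_knots < 1)
    stop("threshold_knots must be >= 1")
  structure(list(classes = classes, hinge_knots = hinge_knots,
                 threshold_knots = threshold_knots),
            class = "feature_basis")
}

# min/max over background rows, per numerical column
fit_feature_scaling <- function(X, numerical_cols) {
  lapply(stats::setNames(numerical_cols, numerical_cols), function(cn)
    c(min = min(X[, cn]), max = max(X[, cn])))
}

scale_features <- function(X, scaling, warn_clip = TRUE) {
  out_of_range <- FALSE
  for (cn in names(scaling)) {
    rg <- scaling[[cn]]
    span <- rg["max"] - rg["min"]
    v <- if (span > 0) (X[, cn] - rg["min"]) / span else rep(0.5, nrow(X))
    if (any(v < -0.5 | v > 1.5)) out_of_range <- TRUE
    X[, cn] <- pmin(pmax(v, -0.5), 1.5)
  }
  if (out_of_range && warn_clip)
    warning("scaled feature values outside [-0.5, 1.5]; clipped")
  X
}

#' Expand features into the MaxEnt basis
#'
#' @param z Numeric matrix (rows = cells) of encoded features, or a single
#'   row as a vector. Column names identify features.
#' @param basis A [feature_basis()].
#' @param scaling Per-numerical-column min/max list fitted on background
#'   rows (see [fit_maxent()]); applied before expansion.
#' @param numerical_cols,categorical_cols Column names by kind; default all
#'   columns numerical.
#' @return Numeric matrix of basis values with descriptive column names.
#' @export
expand_features <- function(z, basis, scaling = NULL,
                            numerical_cols = NULL, categorical_cols = character(0)) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (is.null(numerical_cols)) numerical_cols <- setdiff(colnames(z), categorical_cols)
  if (!is.null(scaling)) z <- scale_features(z, scaling)
  num <- z[, numerical_cols, drop = FALSE]
  out <- list()
  cls <- basis$classes
  if ("linear" %in% cls && ncol(num)) {
    m <- num; colnames(m) <- paste0("lin:", numerical_cols); out$lin <- m
  }
  if ("quadratic" %in% cls && ncol(num)) {
    m <- num^2; colnames(m) <- paste0("quad:", numerical_cols); out$quad <- m
  }
  if ("product" %in% cls && ncol(num) >= 2) {
    cmb <- utils::combn(numerical_cols, 2)
    m <- apply(cmb, 2, function(p) num[, p[1]] * num[, p[2]])
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(z))
    colnames(m) <- apply(cmb, 2, paste, collapse = "*")
    colnames(m) <- paste0("prod:", colnames(m))
    out$prod <- m
  }
  if ("hinge" %in% cls && ncol(num)) {
    knots <- seq_len(basis$hinge_knots) / (basis$hinge_knots + 1)
    cols <- lapply(numerical_cols, function(cn)
      vapply(knots, function(t) pmax(0, num[, cn] - t) / (1 - t), numeric(nrow(z))))
    m <- do.call(cbind, cols)
    colnames(m) <- as.vector(t(outer(numerical_cols, knots,
                                     function(a, b) sprintf("hinge:%s@%.3g", a, b))))
    out$hinge <- m
  }
  if ("threshold" %in% cls && ncol(num)) {
    knots <- seq_len(basis$threshold_knots) / (basis$threshold_knots + 1)
    cols <- lapply(numerical_cols, function(cn)
      vapply(knots, function(t) as.numeric(num[, cn] > t), numeric(nrow(z))))
    m <- do.call(cbind, cols)
    colnames(m) <- as.vector(t(outer(numerical_cols, knots,
                                     function(a, b) sprintf("thr:%s@%.3g", a, b))))
    out$thr <- m
  }
  if ("categorical" %in% cls && length(categorical_cols)) {
    m <- z[, categorical_cols, drop = FALSE]
    colnames(m) <- paste0("cat:", categorical_cols)
    out$cat <- m
  }
  if (!length(out)) stop("basis produced no columns for the given features")
  do.call(cbind, out)
}

# penalized objective: mean over presences of (alpha + h'beta) - sum(lambda|beta|),
# with alpha normalizing the Gibbs weights over the study-area sample Hn
maxent_objective <- function(beta, Hp, Hn, lambda) {
  alpha <- -log_sum_exp(drop(Hn %*% beta))
  mean(drop(Hp %*% beta)) + alpha - sum(lambda * abs(beta))
}

log_sum_exp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit the MaxEnt presence/background model
#'
#' Maximizes the L1-penalized mean log Gibbs density over presence rows,
#' with the normalizer alpha chosen so the Gibbs weights
#' `exp(beta' h(z))` sum to one over the study-area sample — the background
#' rows pooled with the presence rows, the empirical stand-in for the whole
#' cell set (pooling keeps the objective bounded; normalizing over
#' background rows alone diverges whenever a presence lies outside the
#' background's feature support):
#' maximize `mean_p(alpha + beta' h(z_i)) - sum_j lambda_j |beta_j|`.
#' Optimization is proximal gradient ascent (soft-thresholding step) with
#' backtracking; it is deterministic given the inputs. Regularization
#' weights are `lambda_scale * mult_class * sd_j / sqrt(n_presence)` —
#' proportional to the basis column's spread over the pooled sample, so the
#' penalty is scale-equivariant — with multiplier 1 for linear/quadratic/
#' product/categorical terms and 2 for the more flexible hinge/threshold
#' terms.
#'
#' Numerical features are min-max scaled to [0, 1] using background
#' statistics before expansion. Zero-variance basis columns (over the
#' pooled rows) are dropped with a warning. With separable data and
#' `lambda_scale = 0` the objective is unbounded; the iteration then stops
#' at `max_iter` with a warning.
#'
#' @param presence_features,background_features Numeric matrices with
#'   identical column sets (>= 1 presence row, >= 2 background rows).
#' @param basis A [feature_basis()].
#' @param lambda_scale Scale of the L1 penalty (default 1).
#' @param max_iter,tol Stopping rule: objective improvement below `tol` or
#'   `max_iter` proximal steps.
#' @param categorical_cols Names of one-hot indicator columns (excluded
#'   from scaling and continuous expansions).
#' @return Object of class `maxent_model` holding `alpha`, `beta`,
#'   `lambda`, the basis, scaling, calibration constant and fit metadata.
#' @export
fit_maxent <- function(presence_features, background_features,
                       basis = feature_basis(), lambda_scale = 1,
                       max_iter = 3000L, tol = 1e-8,
                       categorical_cols = character(0)) {
  Xp <- as.matrix(presence_features); Xb <- as.matrix(background_features)
  if (nrow(Xp) < 1L || nrow(Xb) < 2L)
    stop("need >= 1 presence and >= 2 background rows")
  if (!identical(colnames(Xp), colnames(Xb)))
    stop("presence and background columns differ")
  numerical_cols <- setdiff(colnames(Xb), categorical_cols)
  # scaling over background plus presence rows, so every basis value lies in
  # [0, 1] during fitting (the clamping convention; presence values outside
  # the background range would otherwise make the objective unbounded)
  scaling <- fit_feature_scaling(rbind(Xb, Xp), numerical_cols)
  Hp <- expand_features(Xp, basis, scaling, numerical_cols, categorical_cols)
  Hb <- expand_features(Xb, basis, scaling, numerical_cols, categorical_cols)
  if (!all(is.finite(Hp)) || !all(is.finite(Hb))) {
    bad <- colnames(Hb)[!apply(rbind(Hp, Hb), 2, function(v) all(is.finite(v)))]
    stop("non-finite basis values in column(s): ", paste(bad, collapse = ", "))
  }
  keep <- apply(rbind(Hp, Hb), 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance basis column(s): ",
            paste(colnames(Hb)[!keep], collapse = ", "))
    Hp <- Hp[, keep, drop = FALSE]; Hb <- Hb[, keep, drop = FALSE]
  }
  if (!ncol(Hb)) stop("no informative basis columns left")

  Hn <- rbind(Hb, Hp)   # study-area sample for the normalizer
  # scale-equivariant penalty: each term pays in proportion to its spread
  mult <- ifelse(grepl("^(hinge|thr):", colnames(Hb)), 2, 1)
  lambda <- lambda_scale * mult * apply(Hn, 2, stats::sd) / sqrt(nrow(Hp))
  beta <- numeric(ncol(Hb))
  hbar <- colMeans(Hp)
  obj <- maxent_objective(beta, Hp, Hn, lambda)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta_n <- drop(Hn %*% beta)
    w <- exp(eta_n - log_sum_exp(eta_n))
    grad <- hbar - drop(crossprod(Hn, w))
    # backtracking proximal ascent
    repeat {
      cand <- beta + step * grad
      cand <- sign(cand) * pmax(abs(cand) - step * lambda, 0)
      new_obj <- maxent_objective(cand, Hp, Hn, lambda)
      d <- cand - beta
      smooth_gain <- sum(grad * d) - sum(d^2) / (2 * step)
      pen_gain <- sum(lambda * (abs(beta) - abs(cand)))
      if (is.finite(new_obj) &&
          new_obj >= obj + smooth_gain + pen_gain - 1e-12) break
      step <- step / 2
      if (step < 1e-12) { new_obj <- obj; cand <- beta; break }
    }
    improve <- new_obj - obj
    beta <- cand; obj <- new_obj
    step <- min(step * 2, 1e3)
    if (improve < tol && it > 1L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MaxEnt did not converge in ", max_iter,
            " iterations (objective may be unbounded, e.g. separable data)")

  alpha <- -log_sum_exp(drop(Hn %*% beta))
  # prevalence calibration targets the background rows only
  cal <- calibrate_prevalence(alpha + drop(Hb %*% beta), prevalence = 0.5)

  structure(list(alpha = alpha, beta = stats::setNames(beta, colnames(Hb)),
                 lambda = stats::setNames(lambda, colnames(Hb)),
                 basis = basis, scaling = scaling,
                 numerical_cols = numerical_cols,
                 categorical_cols = categorical_cols,
                 kept_columns = colnames(Hb),
                 calibration = cal, objective = obj,
                 iterations = it, converged = converged),
            class = "maxent_model")
}

# log constant c with mean(q c / (1 + q c)) over background = prevalence;
# computed in log space as mean(plogis(log q + log c))
calibrate_prevalence <- function(log_q_bg, prevalence = 0.5) {
  f <- function(logc) mean(stats::plogis(log_q_bg + logc)) - prevalence
  lo <- -60; hi <- 60
  while (f(lo) > 0 && lo > -700) lo <- lo - 100
  while (f(hi) < 0 && hi < 700) hi <- hi + 100
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<maxent_model> %d basis terms (%d non-zero), alpha = %.4g, %s\n",
              length(x$beta), nz, x$alpha,
              if (x$converged) sprintf("converged in %d steps", x$iterations)
              else "NOT converged"))
  invisible(x)
}

maxent_log_density <- function(model, X) {
  X <- as.matrix(X)
  H <- expand_features(X, model$basis, model$scaling,
                       model$numerical_cols, model$categorical_cols)
  H <- H[, model$kept_columns, drop = FALSE]
  model$alpha + drop(H %*% model$beta)
}

maxent_raw_density <- function(model, X) exp(maxent_log_density(model, X))

#' Predict relative probability of presence from a MaxEnt fit
#'
#' The raw Gibbs density `q_i = exp(alpha + beta' h(z_i))` is mapped to a
#' bounded relative probability `p*_i = q_i c / (1 + q_i c)` with c chosen
#' at fit time so the mean p* over the background rows equals the assumed
#' prevalence of 0.5 (a prevalence-free quantity is unidentifiable from
#' presence-only data). The raw density is attached as attribute `"raw"`.
#'
#' @param model A [fit_maxent()] result.
#' @param table A `cell_table` (or a raw feature matrix via `features`).
#' @param features Optional feature matrix overriding the table's.
#' @param access_type Label for the returned map.
#' @param drop_layers Passed to [feature_matrix()].
#' @return Object of class `suitability_map`: `access_type`, `p_star`,
#'   `cell_id`, `model_id`.
#' @export
predict_maxent <- function(model, table = NULL, features = NULL,
                           access_type = "unknown", drop_layers = NULL) {
  X <- if (!is.null(features)) as.matrix(features)
       else feature_matrix(table, drop_layers)
  lq <- maxent_log_density(model, X)
  p <- stats::plogis(lq + model$calibration)
  out <- structure(list(access_type = access_type, p_star = p,
                        cell_id = if (!is.null(table)) table$cell_id else NULL,
                        model_id = "maxent"),
                   class = "suitability_map")
  attr(out, "raw") <- exp(lq)
  out
}

#' Score rows with a fitted presence/background model
#'
#' Returns the per-row relative probability of presence in [0, 1] for any
#' supported model class (used by evaluation and permutation importance).
#'
#' @param model A fitted model.
#' @param X Feature matrix with the columns used at fit time.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, X) UseMethod("predict_scores")

#' @export
predict_scores.maxent_model <- function(model, X) {
  stats::plogis(maxent_log_density(model, X) + model$calibration)
}

#' Binary cross-entropy (log loss)
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (1 presence, 0 background).
#' @param eps Clipping bound for probabilities.
#' @return Mean negative log likelihood.
#' @export
log_loss <- function(p, y, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
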