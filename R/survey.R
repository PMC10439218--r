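# Household-survey validation statistics: KS-gated Wilcoxon/t comparison
# of predicted counts between user groups, two-proportion z-test, and the
# minimum representative sample size.

#' Compare model predictions between using and non-using households
#'
#' Every household inherits the predicted expected count of its cell (so
#' households sharing a cell are heavily tied). Each group's values are
#' first checked for normality with a one-sample Kolmogorov-Smirnov test
#' against a normal with the group's estimated mean and SD; if either group
#' departs (p < 0.1), the groups are compared with a two-sided Wilcoxon
#' rank-sum test, otherwise with a two-sample t-test. An empty or
#' zero-variance pair of groups is flagged untestable rather than tested.
#'
#' @param countmap A `count_map` from [scale_to_counts()].
#' @param households data.frame with `household_id`, `cell_id` and logical
#'   `uses_<access_type>` columns.
#' @param access_type Access type to compare.
#' @param ks_p_gate Normality gate (default 0.1).
#' @return Object of class `group_comparison`: group sizes and means, the
#'   test used (`"wilcoxon"`, `"t"` or `"untestable"`), statistic and
#'   two-sided p-value.
#' @export
compare_usage_groups <- function(countmap, households, access_type,
                                 ks_p_gate = 0.1) {
  col <- paste0("uses_", access_type)
  if (!col %in% names(households)) stop("households lack column ", col)
  pred <- countmap$y[match(households$cell_id, countmap$cell_id)]
  if (anyNA(pred)) stop("household cell_id missing from count map")
  uses <- as.logical(households[[col]])
  g1 <- pred[uses]; g0 <- pred[!uses]
  base <- list(access_type = access_type,
               n_using = length(g1), n_not_using = length(g0),
               mean_pred_using = if (length(g1)) mean(g1) else NA_real_,
               mean_pred_not_using = if (length(g0)) mean(g0) else NA_real_)
  untestable <- function(reason) structure(
    c(base, list(test_used = "untestable", statistic = NA_real_,
                 p_value = NA_real_, reason = reason)),
    class = "group_comparison")
  if (!length(g1) || !length(g0)) return(untestable("empty group"))
  if (stats::sd(g1) == 0 && stats::sd(g0) == 0)
    return(untestable("zero-variance groups"))

  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(0)   # degenerate: certainly not normal
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
  }
  normalish <- ks_p(g1) >= ks_p_gate && ks_p(g0) >= ks_p_gate
  if (normalish) {
    tt <- stats::t.test(g1, g0)
    res <- list(test_used = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g0, exact = (length(g1) < 20 &&
                                                length(g0) < 20),
                                              correct = TRUE))
    res <- list(test_used = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(base, res, list(reason = NA_character_)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test_used == "untestable")
    cat(sprintf("<group_comparison> %s: untestable (%s); n = %d vs %d\n",
                x$access_type, x$reason, x$n_using, x$n_not_using))
  else
    cat(sprintf("<group_comparison> %s: %s test, stat %.3f, p %.4f (means %.3f vs %.3f)\n",
                x$access_type, x$test_used, x$statistic, x$p_value,
                x$mean_pred_using, x$mean_pred_not_using))
  invisible(x)
}

#' Two-proportion z-test (pooled)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`. Both the two-sided and the one-sided
#' (direction of the observed difference) p-values are reported.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List `z`, `p_two_sided`, `p_one_sided`, `p1`, `p2`, `pooled`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    stop("pooled proportion is 0 or 1; z statistic undefined")
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z,
       p_two_sided = 2 * stats::pnorm(-abs(z)),
       p_one_sided = stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2, pooled = pool)
}

#' Minimum representative sample size for a finite population
#'
#' `s = chi2 * N_p * P_p (1 - P_p) / (d^2 (N_p - 1) + chi2 * P_p (1 - P_p))`,
#' the classic finite-population correction of the chi-square sample-size
#' guideline. As `N_p` grows the value approaches
#' `chi2 * P_p (1 - P_p) / d^2`, which also bounds it from above.
#'
#' @param chi2 Chi-square value at the desired confidence level for 1 df
#'   (3.841 for 95%).
#' @param n_p Population size (> 0).
#' @param p_p Population proportion in (0, 1); 0.5 maximizes the size.
#' @param d Accuracy as a proportion in (0, 1) (e.g. 0.05).
#' @return List with the `raw` formula value and its `ceiling`.
#' @export
min_sample_size <- function(chi2, n_p, p_p = 0.5, d = 0.05) {
  if (chi2 <= 0 || n_p <= 0) stop("chi2 and n_p must be > 0")
  if (p_p <= 0 || p_p >= 1 || d <= 0 || d >= 1)
    stop("p_p and d must be in (0, 1)")
  raw <- chi2 * n_p * p_p * (1 - p_p) / (d^2 * (n_p - 1) + chi2 * p_p * (1 - p_p))
  list(raw = raw, ceiling = ceiling(raw))
}
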