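# Presence handling and background (pseudo-absence) sampling.

#' Presence-only records for one access type
#'
#' @param access_type Identifier.
#' @param cells Integer vector of 0-based cell ids; duplicates are allowed
#'   (several points can share a cell).
#' @return Object of class `presence_set` with fields `access_type`,
#'   `cells`, `n`.
#' @export
presence_set <- function(access_type, cells) {
  cells <- as.integer(cells)
  structure(list(access_type = as.character(access_type),
                 cells = cells, n = length(cells)),
            class = "presence_set")
}

#' @export
print.presence_set <- function(x, ...) {
  cat(sprintf("<presence_set> %s: %d records in %d cells\n",
              x$access_type, x$n, length(unique(x$cells))))
  invisible(x)
}

background_set <- function(access_type, cells, scheme) {
  structure(list(access_type = as.character(access_type),
                 cells = as.integer(cells), s = length(cells),
                 scheme = scheme),
            class = "background_set")
}

#' Split presence records into training and evaluation parts
#'
#' Record-level random split (a cell with several points can contribute to
#' both parts); training size is `round(train_fraction * n)`, clamped so
#' both parts are non-empty.
#'
#' @param p A [presence_set()] with at least two records.
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @param by_cell If `TRUE`, split distinct cells instead of records, so no
#'   cell appears in both parts (strict leakage control).
#' @return List with `train` and `test` presence sets.
#' @export
split_presences <- function(p, train_fraction = 0.7, seed = 1, by_cell = FALSE) {
  stopifnot(inherits(p, "presence_set"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  units <- if (by_cell) unique(p$cells) else p$cells
  n <- length(units)
  if (n < 2L) stop("need at least 2 presence records to split")
  n_train <- min(max(round(train_fraction * n), 1L), n - 1L)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  if (by_cell) {
    tr_cells <- units[idx]
    train <- p$cells[p$cells %in% tr_cells]
    test <- p$cells[!(p$cells %in% tr_cells)]
  } else {
    train <- units[idx]
    test <- units[-idx]
  }
  list(train = presence_set(p$access_type, train),
       test = presence_set(p$access_type, test))
}

# masked cells carrying no recorded presence of any type
eligible_pool <- function(table, all_presences) {
  used <- unique(unlist(lapply(all_presences, function(p) p$cells)))
  setdiff(table$cell_id, used)
}

draw_background <- function(pool, s, prob = NULL, seed = 1, replace = FALSE) {
  if (!length(pool)) stop("empty eligible background pool")
  set.seed(seed)
  if (!replace && length(pool) < s) {
    warning(sprintf("eligible pool (%d) smaller than requested sample (%d); sampling with replacement",
                    length(pool), s))
    replace <- TRUE
  }
  sample(pool, s, replace = replace, prob = prob)
}

#' Sample a uniform background set
#'
#' Draws `round(ratio * n_presence)` cells uniformly from the masked cells
#' where no presence of any access type is recorded (e.g. 100 presences at
#' ratio 4 give 400 background cells). Sampling is without replacement
#' whenever the pool suffices, otherwise with replacement plus a warning.
#'
#' @param table A `cell_table`.
#' @param all_presences List of [presence_set()]s over all access types
#'   (exclusion is across types).
#' @param n_presence Presence count the ratio applies to.
#' @param ratio Background-to-presence ratio (default 4).
#' @param seed Integer seed.
#' @param access_type Label for the returned set.
#' @return A `background_set` with `scheme = "uniform"`.
#' @export
sample_uniform_background <- function(table, all_presences, n_presence,
                                      ratio = 4, seed = 1,
                                      access_type = "all") {
  pool <- eligible_pool(table, all_presences)
  s <- round(ratio * n_presence)
  cells <- draw_background(pool, s, seed = seed)
  background_set(access_type, cells, "uniform")
}

#' Prior expectation of access points per cell
#'
#' Distributes the estimated total number of access points of one type over
#' cells in proportion to population, separately within the urban and rural
#' strata (the pooled, unstratified form is available via
#' `stratified = FALSE`): `np_i = P_total_j * pop_i / sum(pop in stratum j)`.
#'
#' @param table A `cell_table`.
#' @param totals A [total_presences()] object (or its data.frame).
#' @param access_type Access type to use.
#' @param stratified Stratify by urban/rural (default `TRUE`).
#' @return Object of class `prior_expectation`: `np` (per table row),
#'   `p_total_by_stratum`, `access_type`.
#' @export
compute_prior_expectation <- function(table, totals, access_type,
                                      stratified = TRUE) {
  tot <- as.data.frame(totals)
  tot <- tot[tot$access_type == access_type, , drop = FALSE]
  if (!nrow(tot)) stop("no totals for access type ", access_type)
  np <- numeric(nrow(table))
  p_tot <- c(urban = 0, rural = 0)
  if (stratified) {
    for (st in unique(tot$stratum)) {
      y <- tot$y[tot$stratum == st]
      p_tot[st] <- y
      in_st <- table$stratum == st
      pop_sum <- sum(table$population[in_st])
      if (y > 0 && pop_sum <= 0)
        stop(sprintf("stratum '%s' has positive total but zero population", st))
      if (pop_sum > 0) np[in_st] <- y * table$population[in_st] / pop_sum
    }
  } else {
    y <- sum(tot$y)
    pop_sum <- sum(table$population)
    if (y > 0 && pop_sum <= 0) stop("positive total but zero population")
    np <- y * table$population / pop_sum
    for (st in unique(tot$stratum)) p_tot[st] <- sum(np[table$stratum == st])
  }
  structure(list(access_type = access_type, np = np,
                 cell_id = table$cell_id, p_total_by_stratum = p_tot),
            class = "prior_expectation")
}

#' Weight cells by inverse prior expectation
#'
#' `omega_i = 1 / np_i`; cells with `np_i = 0` (unpopulated areas) receive
#' the maximum weight among cells with positive expectation, not infinity.
#'
#' @param np Non-negative per-cell expected counts.
#' @return Per-cell selection weights (unnormalized).
#' @export
inverse_expectation_weights <- function(np) {
  if (all(np <= 0)) stop("all prior expectations are zero (no populated cells)")
  omega <- ifelse(np > 0, 1 / np, NA_real_)
  omega[is.na(omega)] <- max(omega, na.rm = TRUE)
  omega
}

#' Sample a population-weighted background set
#'
#' Like [sample_uniform_background()], but cells are drawn with selection
#' probability proportional to the inverse of their prior expected number
#' of access points, so background cells resemble true absences more:
#' densely populated cells (expected to hold many points) are avoided.
#'
#' @param prior A [compute_prior_expectation()] result.
#' @inheritParams sample_uniform_background
#' @param replace Force with-replacement draws (default `FALSE`; switches
#'   automatically, with a warning, when the pool is too small).
#' @return A `background_set` with `scheme = "weighted"`.
#' @export
sample_weighted_background <- function(prior, table, all_presences, n_presence,
                                       ratio = 4, seed = 1, replace = FALSE) {
  stopifnot(inherits(prior, "prior_expectation"))
  pool <- eligible_pool(table, all_presences)
  idx <- match(pool, prior$cell_id)
  omega <- inverse_expectation_weights(prior$np)[idx]
  s <- round(ratio * n_presence)
  cells <- draw_background(pool, s, prob = omega, seed = seed, replace = replace)
  background_set(prior$access_type, cells, "weighted")
}
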