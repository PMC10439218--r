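# From access shares to persons-per-source, expected totals, and absolute
# per-cell count maps.

#' Stratified access-share table
#'
#' Share of population whose primary source is each access type, per
#' urban/rural stratum (the DHS-style input). Shares are non-negative and
#' sum to at most 1 within a stratum (a residual share may be unmodelled,
#' e.g. packaged water).
#'
#' @param df data.frame with columns `access_type`, `stratum`
#'   (`"urban"`/`"rural"`), `share`.
#' @return Object of class `access_shares` (a validated data.frame).
#' @export
access_shares <- function(df) {
  stopifnot(all(c("access_type", "stratum", "share") %in% names(df)))
  if (any(df$share < 0)) stop("shares must be >= 0")
  if (!all(df$stratum %in% c("urban", "rural"))) stop("stratum must be urban/rural")
  sums <- tapply(df$share, df$stratum, sum)
  if (any(sums > 1 + 1e-9))
    stop("shares sum to more than 1 within a stratum")
  class(df) <- c("access_shares", "data.frame")
  df
}

#' Persons served per access point, per cell
#'
#' `s_i = pop_i / n_i`, where `n_i` counts the recorded points of all
#' access types in cell i (co-located types share the cell's population).
#' Cells without any recorded point are excluded; the result rests on the
#' assumption that cells with registry data have complete point coverage.
#'
#' @param table A `cell_table`.
#' @param all_presences List of [presence_set()]s across all access types.
#' @return data.frame `cell_id`, `stratum`, `n_points`, `s` (one row per
#'   cell with at least one recorded point).
#' @export
persons_per_point <- function(table, all_presences) {
  pts <- unlist(lapply(all_presences, function(p) p$cells))
  cnt <- table(pts)
  cell_id <- as.integer(names(cnt))
  idx <- match(cell_id, table$cell_id)
  keep <- !is.na(idx)
  cell_id <- cell_id[keep]; idx <- idx[keep]; n_i <- as.integer(cnt)[keep]
  data.frame(cell_id = cell_id,
             stratum = table$stratum[idx],
             n_points = n_i,
             s = table$population[idx] / n_i)
}

#' Average persons per source for one access type
#'
#' Arithmetic mean of the per-cell `s_i` over the cells where the target
#' type is recorded, separately for urban and rural cells. Strata with no
#' qualifying cell are flagged undefined (`NA`). A population-weighted mean
#' is available via `weighted = TRUE`.
#'
#' @param s_cells Output of [persons_per_point()].
#' @param all_presences List of per-type [presence_set()]s.
#' @param access_type Target type.
#' @param table The `cell_table` (for populations when `weighted`).
#' @param weighted Use a population-weighted mean (default `FALSE`).
#' @return Object of class `persons_per_source`: data.frame `access_type`,
#'   `stratum`, `s`, `n_cells_used`.
#' @export
average_persons_per_type <- function(s_cells, all_presences, access_type,
                                     table = NULL, weighted = FALSE) {
  p <- all_presences[[access_type]]
  if (is.null(p)) stop("no presences for access type ", access_type)
  qual <- s_cells[s_cells$cell_id %in% unique(p$cells), , drop = FALSE]
  out <- lapply(c("urban", "rural"), function(st) {
    q <- qual[qual$stratum == st, , drop = FALSE]
    if (!nrow(q)) return(data.frame(access_type = access_type, stratum = st,
                                    s = NA_real_, n_cells_used = 0L))
    s <- if (weighted && !is.null(table)) {
      w <- table$population[match(q$cell_id, table$cell_id)]
      sum(q$s * w) / sum(w)
    } else mean(q$s)
    data.frame(access_type = access_type, stratum = st, s = s,
               n_cells_used = nrow(q))
  })
  out <- do.call(rbind, out)
  class(out) <- c("persons_per_source", "data.frame")
  out
}

#' Total expected presences per access type and stratum
#'
#' `y_{t,j} = share_{t,j} * pop_j / s_{t,j}`: the persons using type t in
#' stratum j (share times stratum population) divided by the persons one
#' point serves. A zero share gives a zero total regardless of s; a
#' positive share with undefined s is an error.
#'
#' @param shares An [access_shares()] table.
#' @param table The `cell_table` (for stratum populations).
#' @param pps A `persons_per_source` data.frame (possibly several types,
#'   rbind-ed).
#' @return Object of class `total_presences`: data.frame `access_type`,
#'   `stratum`, `persons_using`, `s`, `y`.
#' @export
total_expected_presences <- function(shares, table, pps) {
  pop_by <- tapply(table$population, table$stratum, sum)
  rows <- list()
  for (i in seq_len(nrow(shares))) {
    t <- shares$access_type[i]; st <- shares$stratum[i]; sh <- shares$share[i]
    persons_using <- sh * (if (st %in% names(pop_by)) pop_by[[st]] else 0)
    s <- pps$s[pps$access_type == t & pps$stratum == st]
    if (!length(s)) s <- NA_real_
    if (sh == 0) {
      y <- 0
    } else {
      if (is.na(s)) stop(sprintf("positive share but undefined persons-per-source for (%s, %s)", t, st))
      y <- persons_using / s
    }
    rows[[i]] <- data.frame(access_type = t, stratum = st,
                            persons_using = persons_using, s = s, y = y)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("total_presences", "data.frame")
  out
}

#' Scale a relative-probability map to absolute expected counts
#'
#' Within each stratum, `y_i = y_total * p*_i / sum(p* over the stratum)`,
#' so stratum sums are conserved exactly and the presence threshold theta
#' plays no role. Doubling all p* within a stratum leaves the counts
#' unchanged.
#'
#' @param p_star A `suitability_map` (see [predict_maxent()]) or a numeric
#'   vector aligned with `table` rows.
#' @param totals A `total_presences` table for the map's access type.
#' @param table The `cell_table`.
#' @param access_type Access type (defaults to the map's).
#' @return Object of class `count_map`: data.frame `cell_id`, `stratum`,
#'   `y` plus attribute `access_type`.
#' @export
scale_to_counts <- function(p_star, totals, table, access_type = NULL) {
  if (inherits(p_star, "suitability_map")) {
    if (is.null(access_type)) access_type <- p_star$access_type
    p <- p_star$p_star
  } else p <- as.numeric(p_star)
  if (length(p) != nrow(table)) stop("p_star length does not match cell table")
  tot <- as.data.frame(totals)
  if (!is.null(access_type)) tot <- tot[tot$access_type == access_type, , drop = FALSE]
  y <- numeric(nrow(table))
  for (st in unique(tot$stratum)) {
    y_tot <- tot$y[tot$stratum == st]
    in_st <- table$stratum == st
    denom <- sum(p[in_st])
    if (y_tot > 0 && denom <= 0)
      stop(sprintf("stratum '%s' has positive total but all-zero p*", st))
    if (denom > 0) y[in_st] <- y_tot * p[in_st] / denom
  }
  out <- data.frame(cell_id = table$cell_id, stratum = table$stratum, y = y)
  attr(out, "access_type") <- access_type
  class(out) <- c("count_map", "data.frame")
  out
}
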