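#' Define a regular cell lattice
#'
#' A grid of square cells covering the study area. Cells are indexed 0-based,
#' row-major, with cell (0, 0) at the north-west corner; cell extents are
#' half-open and the centre of cell (r, c) lies at ((r + 0.5), (c + 0.5)) *
#' `cell_size` from the origin. A logical mask marks the cells inside the
#' study area (the real-world analogue: cells of a bounding rectangle that
#' fall inside the national border).
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cell_size Cell edge length in km (defaults to 1, i.e. 1 km^2 cells).
#' @param mask Logical vector of length `n_rows * n_cols` (row-major); `TRUE`
#'   marks cells inside the study area. Default: all cells inside.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, mask = NULL) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows <= 0L || n_cols <= 0L)
    stop("grid dimensions must be positive integers")
  n <- n_rows * n_cols
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- as.logical(mask)
  if (length(mask) != n || anyNA(mask))
    stop("mask must be a logical vector of length n_rows * n_cols")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size), mask = mask),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.3g km), %d masked-in\n",
              x$n_rows, x$n_cols, x$cell_size, sum(x$mask)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell id / row-column conversions
#'
#' Cell ids are 0-based row-major: `cell_id = row * n_cols + col`.
#'
#' @param grid A [grid_spec()].
#' @param cell_id Integer vector of 0-based cell ids.
#' @return `cell_rowcol()` returns a data.frame with 0-based `row`, `col`;
#'   `rowcol_cell()` the inverse.
#' @export
cell_rowcol <- function(grid, cell_id) {
  cell_id <- as.integer(cell_id)
  if (any(cell_id < 0L | cell_id >= n_cells(grid)))
    stop("cell_id out of range")
  data.frame(row = cell_id %/% grid$n_cols, col = cell_id %% grid$n_cols)
}

#' @rdname cell_rowcol
#' @param row,col 0-based row/column indices.
#' @export
rowcol_cell <- function(grid, row, col) {
  as.integer(row) * grid$n_cols + as.integer(col)
}

#' Create a typed per-cell feature layer
#'
#' @param name Layer identifier (unique within a stack).
#' @param kind `"numerical"` (real-valued, e.g. precipitation, slope,
#'   distance to water) or `"categorical"` (integer-coded, e.g. soil texture
#'   class, land cover).
#' @param values Per-cell values, row-major, length = number of grid cells.
#' @param nodata Sentinel for missing cells (default `NA`).
#' @return An object of class `feature_layer`.
#' @export
feature_layer <- function(name, kind = c("numerical", "categorical"),
                          values, nodata = NA_real_) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (any(v != round(v))) stop("categorical layer values must be integer codes")
  }
  structure(list(name = as.character(name), kind = kind,
                 values = values, nodata = nodata),
            class = "feature_layer")
}

#' Bundle feature layers on a shared grid
#'
#' @param grid A [grid_spec()].
#' @param layers List of [feature_layer()]s; names must be unique and value
#'   lengths must match the grid.
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(grid, layers) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!length(layers)) stop("feature_stack needs at least one layer")
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop("layer names must be unique")
  for (l in layers) {
    if (!inherits(l, "feature_layer")) stop("layers must be feature_layer objects")
    if (length(l$values) != n_cells(grid))
      stop(sprintf("layer '%s' length does not match grid", l$name))
  }
  names(layers) <- nm
  structure(list(grid = grid, layers = layers), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  kinds <- vapply(x$layers, function(l) l$kind, character(1))
  cat(sprintf("<feature_stack> %d layers (%d numerical, %d categorical) on %d x %d grid\n",
              length(x$layers), sum(kinds == "numerical"),
              sum(kinds == "categorical"), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Resample a feature layer onto another grid
#'
#' Numerical layers are bilinearly interpolated at the destination cell
#' centres; categorical layers take the value of the nearest source cell
#' centre, so no new codes can appear. Both grids are assumed to cover the
#' same geographic extent (the common case of moving native-resolution
#' rasters onto the 1 km^2 analysis lattice).
#'
#' @param layer A [feature_layer()] defined on `src`.
#' @param src,dst Source and destination [grid_spec()]s.
#' @return A [feature_layer()] on `dst`.
#' @export
resample_layer <- function(layer, src, dst) {
  stopifnot(inherits(layer, "feature_layer"),
            inherits(src, "grid_spec"), inherits(dst, "grid_spec"))
  if (length(layer$values) != n_cells(src)) stop("layer does not belong to src grid")
  if (n_cells(src) < 1L || n_cells(dst) < 1L) stop("degenerate grid")
  # destination cell centres in src fractional row/col units (extents equal)
  ids <- 0:(n_cells(dst) - 1L)
  rc <- cell_rowcol(dst, ids)
  fr <- (rc$row + 0.5) * src$n_rows / dst$n_rows - 0.5
  fc <- (rc$col + 0.5) * src$n_cols / dst$n_cols - 0.5
  m <- matrix(layer$values, nrow = src$n_rows, ncol = src$n_cols, byrow = TRUE)
  if (layer$kind == "numerical") {
    r0 <- pmin(pmax(floor(fr), 0), src$n_rows - 1L)
    c0 <- pmin(pmax(floor(fc), 0), src$n_cols - 1L)
    r1 <- pmin(r0 + 1L, src$n_rows - 1L)
    c1 <- pmin(c0 + 1L, src$n_cols - 1L)
    wr <- pmin(pmax(fr - r0, 0), 1)
    wc <- pmin(pmax(fc - c0, 0), 1)
    v00 <- m[cbind(r0 + 1L, c0 + 1L)]
    v01 <- m[cbind(r0 + 1L, c1 + 1L)]
    v10 <- m[cbind(r1 + 1L, c0 + 1L)]
    v11 <- m[cbind(r1 + 1L, c1 + 1L)]
    out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
  } else if (layer$kind == "categorical") {
    rn <- pmin(pmax(round(fr), 0), src$n_rows - 1L)
    cn <- pmin(pmax(round(fc), 0), src$n_cols - 1L)
    out <- m[cbind(rn + 1L, cn + 1L)]
  } else stop("unknown layer kind")
  feature_layer(layer$name, layer$kind, out, nodata = layer$nodata)
}

# pairwise association statistics over masked cells ---------------------------

pearson_r_pair <- function(a, b) stats::cor(a, b)

cramers_v_pair <- function(a, b) {
  tab <- table(a, b)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  k <- min(nrow(tab), ncol(tab)) - 1L
  unname(sqrt(chi2 / (sum(tab) * k)))
}

eta_squared_pair <- function(num, cat) {
  g <- factor(cat)
  if (nlevels(g) < 2L) return(NA_real_)
  gm <- mean(num)
  ss_tot <- sum((num - gm)^2)
  if (ss_tot == 0) return(NA_real_)
  mns <- tapply(num, g, mean)
  ns <- tapply(num, g, length)
  ss_b <- sum(ns * (mns - gm)^2)
  ss_b / ss_tot
}

#' Screen feature layers for collinearity
#'
#' Computes, over masked cells only, Pearson's R for numerical-numerical
#' pairs, Cramer's V for categorical-categorical pairs and eta^2 for mixed
#' pairs. For every pair whose statistic exceeds its threshold, one layer of
#' the pair is dropped: the layer with the larger mean absolute association
#' to all other layers goes (ties drop the later layer in stack order),
#' repeated until no surviving pair exceeds a threshold. A layer constant
#' over the mask renders its Pearson pairs undefined; those pairs are
#' skipped with a warning.
#'
#' @param stack A [feature_stack()] with at least two layers.
#' @param r_max Threshold on `|pearson_r|` (default 0.7).
#' @param v_max Threshold on Cramer's V (default 0.65).
#' @param eta_max Threshold on eta^2 (default 0.7).
#' @return A list with the surviving `stack` and a `report` data.frame of
#'   all computed pair statistics (`layer_a`, `layer_b`, `statistic_name`,
#'   `value`, `dropped_layer`).
#' @export
correlation_screen <- function(stack, r_max = 0.7, v_max = 0.65, eta_max = 0.7) {
  stopifnot(inherits(stack, "feature_stack"))
  if (length(stack$layers) < 2L) stop("need at least two layers to screen")
  msk <- stack$grid$mask
  nms <- names(stack$layers)
  kinds <- vapply(stack$layers, function(l) l$kind, character(1))
  vals <- lapply(stack$layers, function(l) l$values[msk])

  p <- length(nms)
  stat_name <- matrix(NA_character_, p, p)
  stat_val <- matrix(NA_real_, p, p)
  thr <- matrix(NA_real_, p, p)
  const <- vapply(vals, function(v) stats::var(v) == 0 || !is.finite(stats::var(v)), logical(1))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ki <- kinds[i]; kj <- kinds[j]
    if (ki == "numerical" && kj == "numerical") {
      if (const[i] || const[j]) {
        warning(sprintf("Pearson undefined for constant layer pair (%s, %s); pair skipped",
                        nms[i], nms[j]))
        next
      }
      stat_name[i, j] <- "pearson_r"
      stat_val[i, j] <- abs(pearson_r_pair(vals[[i]], vals[[j]]))
      thr[i, j] <- r_max
    } else if (ki == "categorical" && kj == "categorical") {
      stat_name[i, j] <- "cramers_v"
      stat_val[i, j] <- cramers_v_pair(vals[[i]], vals[[j]])
      thr[i, j] <- v_max
    } else {
      num <- if (ki == "numerical") i else j
      cat_ <- if (ki == "numerical") j else i
      stat_name[i, j] <- "eta_squared"
      stat_val[i, j] <- eta_squared_pair(vals[[num]], vals[[cat_]])
      thr[i, j] <- eta_max
    }
  }

  full <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
  sym_val <- full(stat_val)

  alive <- rep(TRUE, p)
  dropped_for <- matrix(NA_character_, p, p)  # pair -> dropped layer
  repeat {
    idx <- which(alive)
    over <- which(!is.na(stat_val) & stat_val > thr, arr.ind = TRUE)
    over <- over[alive[over[, 1]] & alive[over[, 2]], , drop = FALSE]
    if (!nrow(over)) break
    # resolve the worst offending pair first
    o <- over[which.max(stat_val[over]), ]
    i <- o[[1]]; j <- o[[2]]
    mean_assoc <- function(k) mean(abs(sym_val[k, setdiff(idx, k)]), na.rm = TRUE)
    mi <- mean_assoc(i); mj <- mean_assoc(j)
    drop <- if (isTRUE(mi > mj)) i else if (isTRUE(mj > mi)) j else max(i, j)
    alive[drop] <- FALSE
    dropped_for[i, j] <- nms[drop]
  }

  pairs <- which(!is.na(stat_name), arr.ind = TRUE)
  report <- data.frame(
    layer_a = nms[pairs[, 1]],
    layer_b = nms[pairs[, 2]],
    statistic_name = stat_name[pairs],
    value = stat_val[pairs],
    dropped_layer = ifelse(is.na(dropped_for[pairs]), NA_character_, dropped_for[pairs]),
    stringsAsFactors = FALSE
  )
  report <- report[order(report$layer_a, report$layer_b), , drop = FALSE]
  rownames(report) <- NULL
  list(stack = feature_stack(stack$grid, stack$layers[alive]), report = report)
}

#' Build the model-ready cell table
#'
#' One row per masked cell, holding stratum, population and the encoded
#' feature vector: numerical layers pass through unchanged (scaling is a
#' model-side concern); categorical layers are one-hot encoded over their
#' observed codes with no reference category dropped (presence/background
#' discrimination has no identifiability requirement).
#'
#' @param stack A [feature_stack()] of predictor layers.
#' @param population Numerical [feature_layer()] of persons per cell (>= 0).
#' @param strata Categorical [feature_layer()] with codes 0 = urban,
#'   1 = rural (or a layer whose codes are named via `stratum_codes`).
#' @param stratum_codes Named integer vector mapping codes to stratum labels.
#' @return A data.frame of class `cell_table` with columns `cell_id`, `row`,
#'   `col`, `stratum`, `population` and one column per encoded feature;
#'   attribute `feature_info` maps encoded columns to source layers.
#' @export
build_cell_table <- function(stack, population, strata,
                             stratum_codes = c(urban = 0L, rural = 1L)) {
  stopifnot(inherits(stack, "feature_stack"))
  grid <- stack$grid
  if (length(population$values) != n_cells(grid) ||
      length(strata$values) != n_cells(grid))
    stop("population/strata layers do not match the grid")
  if (population$kind != "numerical") stop("population layer must be numerical")
  if (strata$kind != "categorical") stop("strata layer must be categorical")
  msk <- grid$mask
  if (!any(msk)) stop("empty mask: no cells inside the study area")
  ids <- which(msk) - 1L
  pop <- population$values[msk]
  if (any(is.na(pop)) || any(pop < 0)) stop("population must be >= 0 inside the mask")
  scode <- strata$values[msk]
  if (!all(scode %in% stratum_codes))
    stop("unknown stratum code: ", paste(setdiff(unique(scode), stratum_codes), collapse = ", "))
  stratum <- names(stratum_codes)[match(scode, stratum_codes)]

  cols <- list()
  info <- list()
  for (l in stack$layers) {
    v <- l$values[msk]
    if (l$kind == "numerical") {
      if (anyNA(v)) stop(sprintf("layer '%s' has NA inside the mask", l$name))
      cols[[l$name]] <- v
      info[[length(info) + 1L]] <- data.frame(column = l$name, layer = l$name,
                                              kind = "numerical", code = NA_real_)
    } else {
      codes <- sort(unique(v))
      for (cd in codes) {
        cn <- sprintf("%s_%g", l$name, cd)
        cols[[cn]] <- as.numeric(v == cd)
        info[[length(info) + 1L]] <- data.frame(column = cn, layer = l$name,
                                                kind = "categorical", code = cd)
      }
    }
  }
  rc <- cell_rowcol(grid, ids)
  tab <- data.frame(cell_id = ids, row = rc$row, col = rc$col,
                    stratum = stratum, population = pop,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(cols, optional = TRUE))
  attr(tab, "feature_info") <- do.call(rbind, info)
  attr(tab, "grid") <- grid
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Extract the encoded feature matrix from a cell table
#'
#' @param table A `cell_table` from [build_cell_table()].
#' @param drop_layers Optional character vector of source layer names to
#'   exclude (e.g. population density for the weighted-background model).
#' @return Numeric matrix, one row per cell, with the table's cell ids as
#'   rownames.
#' @export
feature_matrix <- function(table, drop_layers = NULL) {
  info <- attr(table, "feature_info")
  keep <- info$column[!(info$layer %in% drop_layers)]
  m <- as.matrix(table[, keep, drop = FALSE])
  rownames(m) <- table$cell_id
  storage.mode(m) <- "double"
  m
}
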