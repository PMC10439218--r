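# Plain-text persistence: per-layer CSVs with a JSON manifest for feature
# stacks and worlds, points CSVs for presence/background sets, JSON model
# dumps.

write_layer_csv <- function(layer, path) {
  utils::write.csv(data.frame(cell_id = seq_along(layer$values) - 1L,
                              value = layer$values),
                   path, row.names = FALSE)
}

read_layer_csv <- function(name, kind, nodata, path, n) {
  df <- utils::read.csv(path)
  if (!all(c("cell_id", "value") %in% names(df)) || nrow(df) != n)
    stop("schema mismatch in layer file ", path)
  v <- df$value[order(df$cell_id)]
  feature_layer(name, kind, v, nodata = nodata)
}

#' Write / read a feature stack as CSV layers plus a JSON manifest
#'
#' Layout: `<dir>/layers.json` (grid dims, cell size, mask, per-layer name,
#' kind and nodata sentinel) and `<dir>/layer_<name>.csv` with columns
#' `cell_id,value`.
#'
#' @param stack A [feature_stack()].
#' @param dir Directory (created if missing).
#' @return `export_stack` returns `dir` invisibly; `import_stack` the
#'   reconstructed stack.
#' @export
export_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$grid
  manifest <- list(
    n_rows = g$n_rows, n_cols = g$n_cols, cell_size = g$cell_size,
    mask = as.integer(g$mask),
    layers = lapply(stack$layers, function(l)
      list(name = l$name, kind = l$kind,
           nodata = if (is.na(l$nodata)) NULL else l$nodata)))
  jsonlite::write_json(manifest, file.path(dir, "layers.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in stack$layers)
    write_layer_csv(l, file.path(dir, paste0("layer_", l$name, ".csv")))
  invisible(dir)
}

#' @rdname export_stack
#' @export
import_stack <- function(dir) {
  mf_path <- file.path(dir, "layers.json")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  grid <- grid_spec(mf$n_rows, mf$n_cols, mf$cell_size,
                    as.logical(unlist(mf$mask)))
  layers <- lapply(mf$layers, function(li) {
    nodata <- if (is.null(li$nodata)) NA_real_ else li$nodata
    read_layer_csv(li$name, li$kind, nodata,
                   file.path(dir, paste0("layer_", li$name, ".csv")),
                   n_cells(grid))
  })
  feature_stack(grid, layers)
}

#' Export a cell table to CSV
#'
#' Columns: `cell_id,row,col,stratum,population,<encoded features>`.
#'
#' @param table A `cell_table`.
#' @param path Output file.
#' @export
export_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
}

#' Write / read presence or background points as CSV
#'
#' Schema `access_type,cell_id` (+ `scheme` for background sets).
#'
#' @param sets List of `presence_set`s or `background_set`s.
#' @param path CSV path.
#' @return `import_points` returns a named list of [presence_set()]s.
#' @export
export_points <- function(sets, path) {
  rows <- lapply(sets, function(p) {
    df <- data.frame(access_type = rep(p$access_type, length(p$cells)),
                     cell_id = p$cells)
    if (!is.null(p$scheme)) df$scheme <- rep(p$scheme, length(p$cells))
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_points
#' @param access_types Types to materialize (empty sets included).
#' @export
import_points <- function(path, access_types = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("access_type", "cell_id") %in% names(df)))
    stop("schema mismatch in points file ", path)
  types <- access_types %||% unique(df$access_type)
  out <- lapply(types, function(t)
    presence_set(t, df$cell_id[df$access_type == t]))
  stats::setNames(out, types)
}

#' Export / import a synthetic world losslessly
#'
#' Directory layout: the feature-stack layout of [export_stack()], plus
#' `population.csv`, `strata.csv`, `true_counts.csv`
#' (`access_type,cell_id,count`), `suitability_<type>.csv`,
#' `presences.csv`, `shares.csv` and `world.json` (config scalars).
#' Import validates the shares (each stratum must sum to 1 within 1e-6).
#'
#' @param world A [generate_world()] result.
#' @param dir Directory.
#' @return `import_world` returns a `world` object equal to the exported
#'   one (the config's suitability spec is restored from JSON).
#' @export
export_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_stack(world$stack, dir)
  write_layer_csv(world$population, file.path(dir, "population.csv"))
  write_layer_csv(world$strata, file.path(dir, "strata.csv"))
  cnt <- do.call(rbind, lapply(names(world$true_counts), function(t) {
    v <- world$true_counts[[t]]
    data.frame(access_type = t, cell_id = seq_along(v) - 1L, count = v)
  }))
  utils::write.csv(cnt[cnt$count > 0, ], file.path(dir, "true_counts.csv"),
                   row.names = FALSE)
  for (t in names(world$true_suitability))
    utils::write.csv(data.frame(cell_id = seq_along(world$true_suitability[[t]]) - 1L,
                                p_star = world$true_suitability[[t]]),
                     file.path(dir, paste0("suitability_", t, ".csv")),
                     row.names = FALSE)
  export_points(world$presences, file.path(dir, "presences.csv"))
  utils::write.csv(as.data.frame(world$shares), file.path(dir, "shares.csv"),
                   row.names = FALSE)
  cfg <- world$config
  jsonlite::write_json(
    list(access_types = cfg$access_types,
         num_names = cfg$num_names, cat_names = cfg$cat_names,
         persons_per_point_true = as.data.frame(cfg$persons_per_point_true),
         detection_rate = cfg$detection_rate,
         bias_strength = cfg$bias_strength,
         pop_meanlog = cfg$pop_meanlog, pop_sdlog = cfg$pop_sdlog,
         urban_quantile = cfg$urban_quantile, field_range = cfg$field_range,
         allocation_sharpness = cfg$allocation_sharpness,
         seed = cfg$seed, suitability_spec = cfg$suitability_spec),
    file.path(dir, "world.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_world
#' @export
import_world <- function(dir) {
  wj <- file.path(dir, "world.json")
  if (!file.exists(wj)) stop("missing manifest: ", wj)
  mf <- jsonlite::read_json(wj, simplifyVector = FALSE)
  stack <- import_stack(dir)
  grid <- stack$grid
  n <- n_cells(grid)
  population <- read_layer_csv("population", "numerical", NA_real_,
                               file.path(dir, "population.csv"), n)
  strata <- read_layer_csv("stratum", "categorical", NA_real_,
                           file.path(dir, "strata.csv"), n)
  types <- unlist(mf$access_types)
  cnt_df <- utils::read.csv(file.path(dir, "true_counts.csv"))
  true_counts <- lapply(types, function(t) {
    v <- integer(n)
    d <- cnt_df[cnt_df$access_type == t, ]
    v[d$cell_id + 1L] <- d$count
    v
  })
  names(true_counts) <- types
  true_suitability <- lapply(types, function(t) {
    d <- utils::read.csv(file.path(dir, paste0("suitability_", t, ".csv")))
    d$p_star[order(d$cell_id)]
  })
  names(true_suitability) <- types
  presences <- import_points(file.path(dir, "presences.csv"), types)
  sh <- utils::read.csv(file.path(dir, "shares.csv"))
  for (st in unique(sh$stratum)) {
    tot <- sum(sh$share[sh$stratum == st])
    if (abs(tot - 1) > 1e-6)
      stop(sprintf("invalid shares: stratum '%s' sums to %.6f, not 1", st, tot))
  }
  shares <- access_shares(sh)
  # the manifest stores one row object per access type
  ppt <- cbind(
    urban = vapply(mf$persons_per_point_true, function(r) as.numeric(r$urban), numeric(1)),
    rural = vapply(mf$persons_per_point_true, function(r) as.numeric(r$rural), numeric(1)))
  rownames(ppt) <- types
  spec <- lapply(mf$suitability_spec, function(sp)
    list(intercept = sp$intercept,
         terms = lapply(sp$terms, function(tm)
           list(layers = unlist(tm$layers), coef = tm$coef))))
  config <- world_config(
    grid = grid,
    n_numeric_layers = length(mf$num_names),
    n_categorical_layers = length(mf$cat_names),
    access_types = types, suitability_spec = spec,
    persons_per_point_true = ppt,
    detection_rate = mf$detection_rate, bias_strength = mf$bias_strength,
    pop_meanlog = mf$pop_meanlog, pop_sdlog = mf$pop_sdlog,
    urban_quantile = mf$urban_quantile, field_range = mf$field_range,
    allocation_sharpness = mf$allocation_sharpness %||% 1,
    seed = mf$seed)
  structure(list(config = config, stack = stack, population = population,
                 strata = strata, true_suitability = true_suitability,
                 true_counts = true_counts, presences = presences,
                 shares = shares),
            class = "world")
}

#' Save / load a fitted model as version-stamped JSON
#'
#' Supports `maxent_model` (basis spec, alpha, beta, lambda, scaling,
#' calibration) and `mlp_model` (architecture plus flattened weights).
#'
#' @param model A fitted model.
#' @param path JSON file path.
#' @return `load_model` returns the reconstructed model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "maxent_model")) {
    payload <- list(format = "aquamap-maxent", version = 1L,
                    alpha = model$alpha, beta = as.list(model$beta),
                    lambda = as.list(model$lambda),
                    basis = unclass(model$basis),
                    scaling = lapply(model$scaling, as.list),
                    numerical_cols = model$numerical_cols,
                    categorical_cols = model$categorical_cols,
                    kept_columns = model$kept_columns,
                    calibration = model$calibration,
                    objective = model$objective,
                    iterations = model$iterations, converged = model$converged)
  } else if (inherits(model, "mlp_model")) {
    payload <- list(format = "aquamap-mlp", version = 1L,
                    layer_sizes = model$layer_sizes,
                    activation = model$activation,
                    W = lapply(model$W, function(w) list(dim = dim(w),
                                                         values = as.numeric(w))),
                    b = model$b, center = as.list(model$center),
                    scale = as.list(model$scale), hyper = model$hyper,
                    training_meta = model$training_meta)
  } else stop("unsupported model class")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(pl$format, "aquamap-maxent")) {
    structure(list(alpha = pl$alpha, beta = unlist(pl$beta),
                   lambda = unlist(pl$lambda),
                   basis = structure(list(classes = pl$basis$classes,
                                          hinge_knots = pl$basis$hinge_knots,
                                          threshold_knots = pl$basis$threshold_knots),
                                     class = "feature_basis"),
                   scaling = lapply(pl$scaling, function(s)
                     c(min = s$min, max = s$max)),
                   numerical_cols = pl$numerical_cols,
                   categorical_cols = pl$categorical_cols %||% character(0),
                   kept_columns = pl$kept_columns,
                   calibration = pl$calibration, objective = pl$objective,
                   iterations = pl$iterations, converged = pl$converged),
              class = "maxent_model")
  } else if (identical(pl$format, "aquamap-mlp")) {
    W <- lapply(pl$W$dim, function(x) x)  # placeholder; rebuilt below
    W <- lapply(seq_len(nrow(pl$W)), function(i)
      matrix(pl$W$values[[i]], pl$W$dim[[i]][1], pl$W$dim[[i]][2]))
    structure(list(W = W, b = pl$b, layer_sizes = pl$layer_sizes,
                   activation = pl$activation, center = unlist(pl$center),
                   scale = unlist(pl$scale), hyper = pl$hyper,
                   training_meta = pl$training_meta),
              class = "mlp_model")
  } else stop("unrecognized model file format")
}
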