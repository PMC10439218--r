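# Synthetic gridded worlds with known ground truth: feature fields,
# clustered population, per-type latent suitability, Poisson access-point
# counts, biased presence-only observation, and a DHS-style share table.

# separable Gaussian blur with edge replication
conv_sep <- function(m, kern) {
  half <- (length(kern) - 1L) %/% 2L
  pad <- function(v) c(rep(v[1L], half), v, rep(v[length(v)], half))
  smooth1 <- function(v) {
    out <- stats::filter(pad(v), kern, sides = 2)
    as.numeric(out[(half + 1L):(half + length(v))])
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

# standardized smoothed Gaussian random field, row-major vector
gaussian_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    half <- max(1L, ceiling(3 * range_cells))
    kern <- stats::dnorm((-half):half, sd = range_cells)
    kern <- kern / sum(kern)
    z <- conv_sep(z, kern)
  }
  v <- as.numeric(t(z))            # row-major
  (v - mean(v)) / stats::sd(v)
}

#' Configure a synthetic world
#'
#' The generator emulates the inputs of a national water-access-point
#' mapping study at desk scale: spatially smooth numerical feature layers,
#' quantile-thresholded categorical layers, a clustered log-normal
#' population surface with an urban/rural stratification, per-access-type
#' latent suitability built from named layers, Poisson access-point counts
#' whose expectation allocates each cell's population across types, and the
#' resulting stratum-wise access-share table.
#'
#' @param grid A [grid_spec()]; default 60 x 60 cells of 1 km.
#' @param n_numeric_layers,n_categorical_layers Numbers of feature layers.
#'   The first five numerical layers are named `dist_water`, `elevation`,
#'   `rainfall`, `poverty`, `slope`; categorical layers `soil`, `landcover`,
#'   ... with 3 codes each. Extra layers get generic names.
#' @param access_types Character vector of access-type identifiers.
#' @param suitability_spec Named list (one element per access type):
#'   `list(intercept =, terms = list(list(layers =, coef =), ...))`. A term's
#'   value is `coef * prod(layer values)`, so a two-layer term is a feature
#'   interaction. Defaults give one linear type, one interaction-driven
#'   type and one mixed type.
#' @param persons_per_point_true Matrix (types x strata `urban`,`rural`) of
#'   true persons served per access point.
#' @param detection_rate Probability that a cell holding true points enters
#'   the presence registry (default 1: complete registry).
#' @param bias_strength Spatial observation bias (>= 0, default 0); see
#'   [observe_presences()].
#' @param pop_meanlog,pop_sdlog Log-normal population parameters per cell.
#' @param urban_quantile Cells with population above this quantile are
#'   classified urban (default 0.85).
#' @param field_range Correlation range (in cells) of the smoothed fields.
#' @param allocation_sharpness Temperature multiplier on the suitability
#'   values before the softmax allocation (default 1); larger values
#'   segregate access types spatially, so most cells are dominated by a
#'   single type.
#' @param seed Integer seed; the whole world is reproducible from it.
#' @return A `world_config` list.
#' @export
world_config <- function(grid = grid_spec(60, 60),
                         n_numeric_layers = 5,
                         n_categorical_layers = 2,
                         access_types = c("borehole", "piped_water", "protected_spring"),
                         suitability_spec = NULL,
                         persons_per_point_true = NULL,
                         detection_rate = 1,
                         bias_strength = 0,
                         pop_meanlog = log(8),
                         pop_sdlog = 1,
                         urban_quantile = 0.85,
                         field_range = 4,
                         allocation_sharpness = 1,
                         seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (detection_rate <= 0 || detection_rate > 1)
    stop("detection_rate must be in (0, 1]")
  if (!length(access_types)) stop("need at least one access type")
  num_names <- c("dist_water", "elevation", "rainfall", "poverty", "slope")
  if (n_numeric_layers > 5)
    num_names <- c(num_names, paste0("num", 6:n_numeric_layers))
  num_names <- num_names[seq_len(n_numeric_layers)]
  cat_names <- c("soil", "landcover")
  if (n_categorical_layers > 2)
    cat_names <- c(cat_names, paste0("cat", 3:n_categorical_layers))
  cat_names <- cat_names[seq_len(n_categorical_layers)]

  if (is.null(suitability_spec)) {
    defaults <- list(
      borehole = list(intercept = 0, terms = list(
        list(layers = "rainfall", coef = 1.8),
        list(layers = "elevation", coef = 1.2))),
      piped_water = list(intercept = 0, terms = list(
        list(layers = c("rainfall", "poverty"), coef = 2.2),
        list(layers = "slope", coef = -0.8))),
      protected_spring = list(intercept = 0, terms = list(
        list(layers = "elevation", coef = 1.5),
        list(layers = "dist_water", coef = -1.8)))
    )
    suitability_spec <- lapply(seq_along(access_types), function(i) {
      if (access_types[i] %in% names(defaults)) defaults[[access_types[i]]]
      else list(intercept = 0, terms = list(
        list(layers = num_names[1 + (i - 1) %% length(num_names)], coef = 1.5)))
    })
    names(suitability_spec) <- access_types
  }
  if (!setequal(names(suitability_spec), access_types))
    stop("suitability_spec must have one element per access type")
  for (sp in suitability_spec) for (tm in sp$terms)
    if (!all(tm$layers %in% c(num_names, cat_names)))
      stop("suitability_spec references unknown layer: ",
           paste(setdiff(tm$layers, c(num_names, cat_names)), collapse = ", "))

  if (is.null(persons_per_point_true)) {
    base <- c(borehole = 75, piped_water = 40, protected_spring = 130)
    pu <- ifelse(access_types %in% names(base), base[access_types], 80)
    persons_per_point_true <- cbind(urban = pu, rural = pu * 1.05)
    rownames(persons_per_point_true) <- access_types
  }
  stopifnot(all(persons_per_point_true > 0),
            nrow(persons_per_point_true) == length(access_types))

  structure(list(grid = grid, num_names = num_names, cat_names = cat_names,
                 access_types = access_types,
                 suitability_spec = suitability_spec,
                 persons_per_point_true = persons_per_point_true,
                 detection_rate = detection_rate,
                 bias_strength = bias_strength,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 urban_quantile = urban_quantile,
                 field_range = field_range,
                 allocation_sharpness = allocation_sharpness,
                 seed = as.integer(seed)),
            class = "world_config")
}

eval_suitability <- function(spec, layers_env) {
  eta <- rep(spec$intercept %||% 0, length(layers_env[[1L]]))
  for (tm in spec$terms) {
    v <- rep(tm$coef, length(eta))
    for (ln in tm$layers) v <- v * layers_env[[ln]]
    eta <- eta + v
  }
  eta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic world
#'
#' Numerical layers are standardized smoothed Gaussian fields; categorical
#' layers are quantile-thresholded fields (3 codes); population is a
#' clustered log-normal surface and cells above the configured population
#' quantile are urban. Each cell's population is allocated across access
#' types by a softmax over the per-type latent suitability, true counts are
#' Poisson with mean `population * weight / persons_per_point`, and the
#' stratum share table is derived from the true served persons
#' (`counts * persons_per_point`), normalized within stratum so shares sum
#' to one. Presences are the registry produced by [observe_presences()]
#' under the configured detection rate and bias.
#'
#' @param config A [world_config()].
#' @return A `world` object: `stack`, `population`, `strata` (layers),
#'   `true_suitability` and `true_counts` (named per-type lists of per-cell
#'   vectors), `presences` (per-type [presence_set()]s), `shares`
#'   ([access_shares()]), and the `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  grid <- config$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  if (nr <= 0 || nc <= 0) stop("non-positive grid")
  set.seed(config$seed)

  layers <- list()
  fields <- list()
  for (nm in config$num_names) {
    fields[[nm]] <- gaussian_field(nr, nc, config$field_range)
    layers[[nm]] <- feature_layer(nm, "numerical", fields[[nm]])
  }
  for (nm in config$cat_names) {
    f <- gaussian_field(nr, nc, config$field_range)
    codes <- as.numeric(cut(f, breaks = stats::quantile(f, c(0, 1/3, 2/3, 1)),
                            include.lowest = TRUE, labels = FALSE)) - 1
    fields[[nm]] <- codes
    layers[[nm]] <- feature_layer(nm, "categorical", codes)
  }
  stack <- feature_stack(grid, layers)

  pop_f <- gaussian_field(nr, nc, config$field_range * 1.5)
  pop <- exp(config$pop_meanlog + config$pop_sdlog * pop_f)
  population <- feature_layer("population", "numerical", pop)
  urban_thr <- stats::quantile(pop[grid$mask], config$urban_quantile)
  strata_code <- ifelse(pop > urban_thr, 0, 1)   # 0 urban, 1 rural
  strata <- feature_layer("stratum", "categorical", strata_code)
  stratum_lab <- ifelse(strata_code == 0, "urban", "rural")

  types <- config$access_types
  eta <- vapply(types, function(t)
    eval_suitability(config$suitability_spec[[t]], fields),
    numeric(nr * nc))
  # softmax allocation of each cell's population across access types
  eta <- eta * config$allocation_sharpness
  eta_c <- eta - apply(eta, 1L, max)
  w <- exp(eta_c) / rowSums(exp(eta_c))

  persons <- config$persons_per_point_true
  intensity <- matrix(0, nr * nc, length(types), dimnames = list(NULL, types))
  for (k in seq_along(types)) {
    s_cell <- persons[k, ifelse(stratum_lab == "urban", "urban", "rural")]
    intensity[, k] <- pop * w[, k] / s_cell
  }
  true_counts <- lapply(seq_along(types), function(k) {
    cnt <- stats::rpois(nr * nc, intensity[, k])
    cnt[!grid$mask] <- 0L
    cnt
  })
  names(true_counts) <- types
  true_suitability <- lapply(seq_along(types), function(k) {
    s <- intensity[, k] / max(intensity[grid$mask, k])
    s[!grid$mask] <- NA_real_
    s
  })
  names(true_suitability) <- types

  # stratum share table from true served persons
  share_rows <- list()
  for (st in c("urban", "rural")) {
    in_st <- grid$mask & (stratum_lab == st)
    served <- vapply(seq_along(types), function(k)
      sum(true_counts[[k]][in_st]) * persons[k, st], numeric(1))
    tot <- sum(served)
    sh <- if (tot > 0) served / tot else rep(0, length(types))
    share_rows[[st]] <- data.frame(access_type = types, stratum = st,
                                   share = sh, stringsAsFactors = FALSE)
  }
  shares <- access_shares(do.call(rbind, share_rows))

  world <- structure(list(config = config, stack = stack,
                          population = population, strata = strata,
                          true_suitability = true_suitability,
                          true_counts = true_counts,
                          presences = NULL, shares = shares),
                     class = "world")
  world$presences <- lapply(types, function(t)
    observe_presences(world, t, config$detection_rate, config$bias_strength,
                      seed = config$seed + match(t, types)))
  names(world$presences) <- types
  world
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world> %d x %d grid, %d layers, %d access types\n",
              x$config$grid$n_rows, x$config$grid$n_cols,
              length(x$stack$layers), length(x$config$access_types)))
  for (t in x$config$access_types)
    cat(sprintf("  %-18s true points %6d in %5d cells, %5d presence records\n",
                t, sum(x$true_counts[[t]]), sum(x$true_counts[[t]] > 0),
                x$presences[[t]]$n))
  invisible(x)
}

#' Observe a biased presence-only registry
#'
#' Each cell holding at least one true point of the access type enters the
#' registry independently with probability `detection_rate * b_i`, where
#' `b_i` is a spatial bias factor decaying with distance from a randomly
#' placed survey centre: `b_i = exp(-bias_strength * d_i / d_max)`
#' (so `b_i == 1` everywhere when `bias_strength = 0`). A detected cell
#' contributes one presence record per true point in it, so record
#' multiplicity reflects point counts; no absences are recorded.
#'
#' @param world A [generate_world()] result.
#' @param access_type One of the world's access types.
#' @param detection_rate Detection probability in (0, 1].
#' @param bias_strength Non-negative distance-decay strength.
#' @param seed Integer seed.
#' @return A [presence_set()].
#' @export
observe_presences <- function(world, access_type, detection_rate = 1,
                              bias_strength = 0, seed = 1) {
  stopifnot(inherits(world, "world"))
  if (!(access_type %in% world$config$access_types))
    stop("unknown access type: ", access_type)
  if (detection_rate <= 0 || detection_rate > 1)
    stop("detection_rate must be in (0, 1]")
  grid <- world$config$grid
  cnt <- world$true_counts[[access_type]]
  true_cells <- which(cnt > 0L) - 1L
  set.seed(seed)
  if (bias_strength > 0) {
    centre <- c(stats::runif(1, 0, grid$n_rows), stats::runif(1, 0, grid$n_cols))
    rc <- cell_rowcol(grid, true_cells)
    d <- sqrt((rc$row + 0.5 - centre[1])^2 + (rc$col + 0.5 - centre[2])^2)
    d_max <- sqrt(grid$n_rows^2 + grid$n_cols^2)
    b <- exp(-bias_strength * d / d_max)
  } else b <- rep(1, length(true_cells))
  keep <- stats::runif(length(true_cells)) < detection_rate * b
  det <- true_cells[keep]
  cells <- rep(det, cnt[det + 1L])
  presence_set(access_type, cells)
}

#' Simulate household survey records over a world
#'
#' Draws households in populated cells (selection probability proportional
#' to population) and flags usage of each access type with probability
#' increasing in the cell's true count of that type (a household next to
#' more springs is more likely to report using springs). A convenience for
#' exercising the survey-comparison stage; it does not emulate any real
#' sampling design.
#'
#' @param world A [generate_world()] result.
#' @param n_households Number of households.
#' @param n_cells Number of distinct surveyed cells.
#' @param seed Integer seed.
#' @return data.frame with `household_id`, `cell_id` and one logical
#'   `uses_<type>` column per access type.
#' @export
simulate_households <- function(world, n_households = 500, n_cells = 20, seed = 1) {
  grid <- world$config$grid
  pop <- world$population$values
  set.seed(seed)
  eligible <- which(grid$mask) - 1L
  probs <- pop[eligible + 1L]
  cells <- sample(eligible, min(n_cells, length(eligible)), prob = probs)
  hh_cell <- sample(cells, n_households, replace = TRUE)
  out <- data.frame(household_id = seq_len(n_households), cell_id = hh_cell)
  for (t in world$config$access_types) {
    cnt <- world$true_counts[[t]][hh_cell + 1L]
    p_use <- 1 - exp(-0.5 * cnt)
    out[[paste0("uses_", t)]] <- stats::runif(n_households) < p_use
  }
  out
}
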