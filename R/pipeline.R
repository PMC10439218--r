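# End-to-end orchestration: simulate/ingest -> screen -> split -> sample
# background -> train -> predict -> scale -> evaluate, with one master seed
# deriving every stage seed and a manifest recording them.

#' Configure a pipeline run
#'
#' Defaults encode the reference analysis settings: background ratio 4,
#' 70/30 presence split, presence threshold 0.3, stratified weighted
#' backgrounds, and a small random hyperparameter search for the MLPs.
#'
#' @param world_source A `world` object, a [world_config()] (generated at
#'   run time), or a directory path accepted by [import_world()].
#' @param access_types Types to model; default all in the world.
#' @param models Subset of `"maxent"`, `"mlp"`, `"mlp-weighted"`.
#' @param ratio Background-to-presence ratio (default 4).
#' @param theta Presence threshold (default 0.3).
#' @param train_fraction Presence split (default 0.7).
#' @param search A [hyper_search_space()] for the MLP models, or `NULL` to
#'   fit a fixed single configuration.
#' @param basis A [feature_basis()] for MaxEnt.
#' @param mlp_args List of [fit_mlp()] arguments used when `search` is
#'   `NULL` (default a single 10-unit relu layer, 300 epochs).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(world_source, access_types = NULL,
                       models = c("maxent", "mlp", "mlp-weighted"),
                       ratio = 4, theta = 0.3, train_fraction = 0.7,
                       search = NULL, basis = feature_basis(),
                       mlp_args = list(hidden = c(10), activation = "relu",
                                       max_iter = 300),
                       seed = 1, out_dir = tempfile("aquamap_run_")) {
  models <- match.arg(models, c("maxent", "mlp", "mlp-weighted"),
                      several.ok = TRUE)
  structure(list(world_source = world_source, access_types = access_types,
                 models = models, ratio = ratio, theta = theta,
                 train_fraction = train_fraction, search = search,
                 basis = basis, mlp_args = mlp_args,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

derive_seeds <- function(master, labels) {
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

#' Run the full analysis pipeline
#'
#' Per access type and model: collinearity screening of the feature stack,
#' 70/30 presence split, background sampling (uniform; the weighted scheme
#' additionally excludes the population-density feature from the model so
#' the classifier cannot collapse onto a people-detector), training,
#' prediction of the relative-probability map, scaling to absolute counts
#' via the share table, and TPR/FPR/AUC evaluation on the held-out
#' presences plus a fresh evaluation background. Writes per-(type, model)
#' count maps (CSV), evaluation reports (JSON), a Table-1-style summary
#' CSV and a manifest of all derived stage seeds; the same config and seed
#' reproduce every output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `out_dir`, `manifest`, per-(type, model)
#'   `results` (`suitability`, `counts`, `eval`), and the screened table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  world <- config$world_source
  if (is.character(world)) world <- import_world(world)
  if (inherits(world, "world_config")) world <- generate_world(world)
  stopifnot(inherits(world, "world"))
  types <- config$access_types %||% world$config$access_types

  stage("screen", "collinearity screening")
  scr <- correlation_screen(world$stack)
  stage("screen", sprintf("%d of %d layers survive",
                          length(scr$stack$layers), length(world$stack$layers)))
  table <- build_cell_table(scr$stack, world$population, world$strata)
  stage("table", sprintf("%d masked cells, %d encoded features",
                         nrow(table), ncol(feature_matrix(table))))

  seeds <- derive_seeds(config$seed, c(
    as.vector(outer(types, c("split", "bg", "bg_eval", "train", "search"),
                    paste, sep = "."))))
  X_std <- cbind(feature_matrix(table), population = table$population)
  X_wtd <- feature_matrix(table)   # population feature excluded

  # persons-per-source over every registered type (the share table covers
  # them all), even when only a subset is modelled
  pps_cells <- persons_per_point(table, world$presences)
  pps <- do.call(rbind, lapply(world$config$access_types, function(t)
    average_persons_per_type(pps_cells, world$presences, t)))
  totals <- total_expected_presences(world$shares, table, pps)

  results <- list()
  summary_rows <- list()
  for (t in types) {
    p <- world$presences[[t]]
    if (is.null(p) || p$n < 2L) stop("stage split: too few presences for ", t)
    sp <- split_presences(p, config$train_fraction, seed = seeds[[paste0(t, ".split")]])
    stage("split", sprintf("%s: %d train / %d test records", t, sp$train$n, sp$test$n))
    row_of <- function(cells) match(cells, table$cell_id)

    bg_u <- sample_uniform_background(table, world$presences, sp$train$n,
                                      ratio = config$ratio,
                                      seed = seeds[[paste0(t, ".bg")]],
                                      access_type = t)
    prior <- compute_prior_expectation(table, totals, t)
    bg_w <- sample_weighted_background(prior, table, world$presences, sp$train$n,
                                       ratio = config$ratio,
                                       seed = seeds[[paste0(t, ".bg")]] + 1L)
    bg_ev <- sample_uniform_background(table, world$presences, sp$test$n,
                                       ratio = config$ratio,
                                       seed = seeds[[paste0(t, ".bg_eval")]],
                                       access_type = t)
    stage("background", sprintf("%s: %d uniform, %d weighted, %d eval cells",
                                t, bg_u$s, bg_w$s, bg_ev$s))

    for (m in config$models) {
      weighted <- m == "mlp-weighted"
      X <- if (weighted) X_wtd else X_std
      bg <- if (weighted) bg_w else bg_u
      Xp_tr <- X[row_of(sp$train$cells), , drop = FALSE]
      Xb_tr <- X[row_of(bg$cells), , drop = FALSE]
      fit_seed <- seeds[[paste0(t, ".train")]]
      model <- if (m == "maxent") {
        fit_maxent(Xp_tr, Xb_tr, basis = config$basis)
      } else if (!is.null(config$search)) {
        hyperparameter_search(config$search, Xp_tr, Xb_tr,
                              seed = seeds[[paste0(t, ".search")]],
                              eval_presence = X[row_of(sp$test$cells), , drop = FALSE],
                              eval_background = X[row_of(bg_ev$cells), , drop = FALSE])$model
      } else {
        do.call(fit_mlp, c(list(Xp_tr, Xb_tr, seed = fit_seed), config$mlp_args))
      }
      stage("train", sprintf("%s/%s fitted", t, m))

      p_star <- structure(list(access_type = t,
                               p_star = predict_scores(model, X),
                               cell_id = table$cell_id, model_id = m),
                          class = "suitability_map")
      counts <- scale_to_counts(p_star, totals, table, access_type = t)
      ev <- eval_report(predict_scores(model, X[row_of(sp$test$cells), , drop = FALSE]),
                        predict_scores(model, X[row_of(bg_ev$cells), , drop = FALSE]),
                        theta = config$theta, access_type = t, model_id = m)
      stage("evaluate", sprintf("%s/%s: TPR %.3f FPR %.3f AUC %.3f",
                                t, m, ev$tpr, ev$fpr, ev$auc))

      key <- paste(t, m, sep = ".")
      results[[key]] <- list(model = model, suitability = p_star,
                             counts = counts, eval = ev)
      utils::write.csv(data.frame(cell_id = counts$cell_id, access_type = t,
                                  expected_count = counts$y),
                       file.path(config$out_dir, sprintf("counts_%s_%s.csv", t, m)),
                       row.names = FALSE)
      jsonlite::write_json(unclass(ev),
                           file.path(config$out_dir, sprintf("eval_%s_%s.json", t, m)),
                           auto_unbox = TRUE, digits = NA)
      summary_rows[[key]] <- data.frame(access_type = t, model = m, n = ev$n,
                                        tpr = ev$tpr, fpr = ev$fpr, auc = ev$auc)
    }
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(config$out_dir, "performance_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(totals),
                   file.path(config$out_dir, "expected_totals.csv"),
                   row.names = FALSE)
  manifest <- list(master_seed = config$seed, stage_seeds = as.list(seeds),
                   models = config$models, access_types = types,
                   ratio = config$ratio, theta = config$theta,
                   train_fraction = config$train_fraction,
                   screened_layers = names(scr$stack$layers),
                   package_version = as.character(utils::packageVersion("aquamap")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 results = results, table = table, totals = totals,
                 screen_report = scr$report))
}

stage <- function(name, msg) message(sprintf("[%s] %s", name, msg))
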