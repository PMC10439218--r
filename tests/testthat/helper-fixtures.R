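# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# the default desk-scale study world
default_world <- function() memo("world60", generate_world(world_config(seed = 42)))

default_table <- function() memo("table60", world_cell_table(default_world()))

# feature matrix including population (the standard-model view)
default_features <- function() memo("X60", {
  tab <- default_table()
  cbind(feature_matrix(tab), population = tab$population)
})

categorical_columns <- function(tab) {
  info <- attr(tab, "feature_info")
  info$column[info$kind == "categorical"]
}

# small 20x20 world for cheap structural tests
small_world <- function() memo("world20",
  generate_world(world_config(grid = grid_spec(20, 20), pop_meanlog = log(40),
                              seed = 7)))

# a tiny hand-built cell table: 2 numerical layers, 6x6 grid
tiny_table <- function(seed = 1) {
  set.seed(seed)
  g <- grid_spec(6, 6)
  st <- feature_stack(g, list(
    feature_layer("a", "numerical", rnorm(36)),
    feature_layer("b", "numerical", rnorm(36))))
  pop <- feature_layer("population", "numerical", rep(10, 36))
  strat <- feature_layer("stratum", "categorical", rep(c(0, 1), each = 18))
  build_cell_table(st, pop, strat)
}
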