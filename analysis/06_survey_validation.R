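#!/usr/bin/env Rscript
# Stage 6: validate count maps against simulated household-survey usage,
# and report the survey-statistics toolkit (KS-gated Wilcoxon/t comparison,
# two-proportion z-test, minimum representative sample size).

library(aquamap)

world <- import_world("results/world")
tab <- world_cell_table(world)

# model predictions from stage 3
run_dir <- "results/run"
hh <- simulate_households(world, n_households = 500, n_cells = 25, seed = 99)

rows <- list()
for (t in world$config$access_types) {
  cm_df <- read.csv(file.path(run_dir, sprintf("counts_%s_mlp.csv", t)))
  cm <- structure(data.frame(cell_id = cm_df$cell_id,
                             stratum = tab$stratum[match(cm_df$cell_id, tab$cell_id)],
                             y = cm_df$expected_count),
                  class = c("count_map", "data.frame"))
  gc <- compare_usage_groups(cm, hh, t)
  print(gc)
  rows[[t]] <- data.frame(access_type = t, n_using = gc$n_using,
                          n_not_using = gc$n_not_using,
                          mean_pred_using = gc$mean_pred_using,
                          mean_pred_not_using = gc$mean_pred_not_using,
                          test = gc$test_used, statistic = gc$statistic,
                          p_value = gc$p_value)
}
write.csv(do.call(rbind, rows), "results/survey_comparison.csv", row.names = FALSE)

# health-risk style proportion comparison on the simulated survey:
# households using the interaction-driven type vs the rest, by usage of a
# second type (illustrates the z-test mechanics on real group sizes)
u1 <- hh$uses_piped_water
x1 <- sum(hh$uses_borehole[u1]); n1 <- sum(u1)
x2 <- sum(hh$uses_borehole[!u1]); n2 <- sum(!u1)
zt <- two_proportion_ztest(x1, n1, x2, n2)
cat(sprintf("\nz-test borehole usage by piped usage: z = %.2f, two-sided p = %.3f\n",
            zt$z, zt$p_two_sided))

ss <- min_sample_size(chi2 = 3.841, n_p = 50000, p_p = 0.5, d = 0.05)
cat(sprintf("minimum representative sample size for 50k households: %.1f (ceiling %d)\n",
            ss$raw, ss$ceiling))
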