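#!/usr/bin/env Rscript
# Stage 2: collinearity screening of the feature stack.
#
# Pairwise association over masked cells — Pearson's R (numerical pairs),
# Cramer's V (categorical pairs), eta^2 (mixed) — dropping one layer of any
# pair above threshold, the way highly correlated groundwater or distance
# layers would be pruned before modelling.

library(aquamap)

world <- import_world("results/world")
scr <- correlation_screen(world$stack)

cat("surviving layers:", paste(names(scr$stack$layers), collapse = ", "), "\n\n")
print(scr$report, digits = 3)
write.csv(scr$report, "results/screen_report.csv", row.names = FALSE)

dropped <- unique(stats::na.omit(scr$report$dropped_layer))
cat("\ndropped:", if (length(dropped)) paste(dropped, collapse = ", ") else "none", "\n")
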