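#!/usr/bin/env Rscript
# Simulate the study landscape and the vegetation plot database.
#
# Generates two latent landscape gradients (a moisture axis and a mesic/
# drained axis), derives occupancy and expected-cover surfaces for the six
# species presets, and samples 500 stratified-random plots measured by
# 150-point line-point intercept. Writes the plot table and a summary of
# prevalence and dominance structure.

source(file.path("analysis", "00_common.R"))

truth <- landscape_truth()
plots <- plot_table(truth)

write_plot_table(plots, file.path(RESULTS_DIR, "plots.csv"))
write_stack(truth$gradients, GRID, file.path(RESULTS_DIR, "gradients"))

prev <- tapply(plots$present, plots$species, mean)
nz <- plots$cover_pct[plots$cover_pct > 0]
summary <- data.frame(
  species = names(prev),
  observed_prevalence_pct = round(100 * as.numeric(prev), 1),
  mean_cover_pct = round(tapply(plots$cover_pct, plots$species, mean), 2)
)
write.csv(summary, file.path(RESULTS_DIR, "plot_summary.csv"),
          row.names = FALSE)

cat(sprintf("plots: %d sites x %d species\n",
            length(unique(plots$site_id)), length(unique(plots$species))))
print(summary, row.names = FALSE)
cat(sprintf("nonzero observations >25%% cover: %.1f%%; >50%%: %.1f%%\n",
            100 * mean(nz > 25), 100 * mean(nz > 50)))
cat(sprintf("zero-inflation: %.1f%% of all observations are zeros\n",
            100 * mean(plots$cover_pct == 0)))
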