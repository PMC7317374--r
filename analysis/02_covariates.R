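#!/usr/bin/env Rscript
# Build the model covariate stack: 18 environmental layers (terrain,
# hydrography, wetness, climate surrogates) plus 65 spectral layers (7
# reflectance bands and 6 indices for each of May-September, composited by
# maximum NDVI across years with nearest-neighbor gap filling).

source(file.path("analysis", "00_common.R"))

truth <- landscape_truth()
stack <- covariate_stack(truth)

cat(sprintf("covariate stack: %d layers (%d environmental + %d spectral)\n",
            length(stack), 18, length(stack) - 18))

summary <- data.frame(
  layer = names(stack),
  min = round(vapply(stack, min, numeric(1)), 4),
  mean = round(vapply(stack, mean, numeric(1)), 4),
  max = round(vapply(stack, max, numeric(1)), 4)
)
write.csv(summary, file.path(RESULTS_DIR, "covariate_summary.csv"),
          row.names = FALSE)
write_stack(stack[c("elevation", "slope", "compound_topographic_index",
                    "dist_small_streams", "jul_ndvi")],
            GRID, file.path(RESULTS_DIR, "covariates"))
cat("wrote covariate_summary.csv and example layers under",
    file.path(RESULTS_DIR, "covariates"), "\n")
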