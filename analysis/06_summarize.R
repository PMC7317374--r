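#!/usr/bin/env Rscript
# Final spatial prediction and regional summaries for the wetland-dominant
# species: classifier and regressor trained on all plots (hyperparameters
# and threshold from the same inner cross-validation scheme), predicted
# over the study area, then summarized as cover-weighted vegetation area
# per region (900 m2 per cell) and the 95% interval of predicted cover
# where presence is predicted.

source(file.path("analysis", "00_common.R"))

truth <- landscape_truth()
plots <- plot_table(truth)
stack <- covariate_stack(truth)

site_rows <- !duplicated(plots$site_id)
obs <- vapply(names(stack), function(nm)
  stack[[nm]][cbind(plots$row[site_rows], plots$col[site_rows])],
  numeric(sum(site_rows)))
sa <- delineate_study_area(obs, stack, study_area_config(window_cells = 15))

sp <- "wetland_dominant"
dat <- stack_at_plots(stack, plots[plots$species == sp, ])
res <- train_final_and_predict_raster(
  dat, names(stack), stack, mask = sa$mask,
  scheme = cv_scheme(10, 10, seed = derive_seed(MASTER_SEED, "cv")),
  opt = bayes_opt_config(6, 3, seed = derive_seed(MASTER_SEED, "opt")),
  space_classifier = hyperparameter_space("classifier", fast = TRUE),
  space_regressor = hyperparameter_space("regressor", fast = TRUE))

write_ascii_grid(res$cover, GRID,
                 file.path(RESULTS_DIR, sprintf("cover_%s.asc", sp)))
write_ascii_grid(res$distribution, GRID,
                 file.path(RESULTS_DIR, sprintf("distribution_%s.asc", sp)))

# two synthetic "ecoregions": the wetter and drier halves of gradient 1
regions <- matrix(ifelse(truth$gradients[[1]] >
                           median(truth$gradients[[1]]),
                         "wet_lowland", "dry_upland"),
                  GRID$n_rows, GRID$n_cols)
areas <- area_summary(res$cover, regions, GRID)
write.csv(areas, file.path(RESULTS_DIR, "areas.csv"), row.names = FALSE)
print(as.data.frame(areas), row.names = FALSE)

ci <- presence_cover_interval(res$cover, res$distribution)
cat(sprintf(paste0("where presence is predicted, 95%% of predicted cover ",
                   "is between %.0f%% and %.0f%%\n"), ci[1], ci[2]))
write.csv(data.frame(species = sp, p2.5 = ci[1], p97.5 = ci[2]),
          file.path(RESULTS_DIR, "cover_interval.csv"), row.names = FALSE)
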