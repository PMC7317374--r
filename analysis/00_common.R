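# Shared settings for the analysis drivers. Every script regenerates its
# inputs deterministically from MASTER_SEED, so the scripts can be run
# independently or in sequence and always agree.

library(foliarmap)

MASTER_SEED <- 20260920L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

GRID <- grid_spec(64, 64)        # 1.92 x 1.92 km of 30 m cells
N_PLOTS <- 500L

landscape_truth <- function() {
  simulate_landscape(GRID, make_species_presets(), n_gradients = 2,
                     correlation_length_cells = 8,
                     seed = derive_seed(MASTER_SEED, "landscape"))
}

plot_table <- function(truth) {
  sample_plots(truth, sampling_design(N_PLOTS, "stratified_random",
                                      seed = derive_seed(MASTER_SEED,
                                                         "plots")))
}

covariate_stack <- function(truth) {
  dem <- 100 + 40 * generate_latent_gradients(
    GRID, 1, 10, seed = derive_seed(MASTER_SEED, "dem"))[[1]] +
    matrix(rep(seq(0, 30, length.out = GRID$n_rows), GRID$n_cols),
           GRID$n_rows, GRID$n_cols)
  climate <- generate_latent_gradients(GRID, 5, 12,
                                       seed = derive_seed(MASTER_SEED,
                                                          "climate"))
  names(climate) <- c("date_of_freeze", "date_of_thaw",
                      "growing_season_length", "summer_warmth_index",
                      "annual_precipitation")
  env <- build_environmental_stack(dem, GRID, climate_layers = climate)
  comps <- lapply(spectral_months(), function(m) {
    impute_gaps(max_ndvi_composite(
      simulate_scenes(truth$gradients, GRID, m,
                      seed = derive_seed(MASTER_SEED, "scenes"))), GRID)
  })
  c(env, build_spectral_stack(comps))
}

stack_at_plots <- function(stack, plots) {
  idx <- cbind(plots$row, plots$col)
  covs <- vapply(names(stack), function(nm) stack[[nm]][idx],
                 numeric(nrow(plots)))
  cbind(plots, tibble::as_tibble(covs))
}
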