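# End-to-end orchestration: one master seed derives a named substream per
# stage, so stages are independently reproducible and two runs of the same
# configuration produce byte-identical artifacts.

#' Derive a stage seed from the master seed
#'
#' Stable string hash of the stage name folded into the master seed, kept
#' inside the 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master_seed)) %% 2147483647)
}

#' Build a pipeline run configuration
#'
#' The bundled defaults are a desk-scale configuration: a 32 x 32 grid, 200
#' plots, two species and a reduced optimization budget. Unknown keys in
#' `...` are rejected.
#'
#' @param out_dir Output directory for artifacts.
#' @param master_seed Master seed; every stage seed derives from it.
#' @param ... Overrides for: `n_rows`, `n_cols`, `n_plots`, `species`
#'   (preset names), `correlation_length_cells`, `outer_k`, `inner_k`,
#'   `n_initial_points`, `n_iterations`, `n_classes`, `latitude_deg`,
#'   `evi2_formula`, `fast_space`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("foliarmap_run_"),
                       master_seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, master_seed = as.integer(master_seed),
    n_rows = 32L, n_cols = 32L, n_plots = 200L,
    species = c("wetland_dominant", "mesic_dominant"),
    correlation_length_cells = 6,
    outer_k = 10L, inner_k = 10L,
    n_initial_points = 6L, n_iterations = 2L,
    n_classes = 25L, latitude_deg = 70,
    evi2_formula = "jiang2008", fast_space = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "run_config"
  cfg
}

# Synthetic elevation for the terrain stage: a smooth field with ~80 m of
# relief plus a gentle regional tilt so streams drain coherently.
synthesize_dem <- function(spec, seed) {
  g <- generate_latent_gradients(spec, 1, correlation_length_cells = 10,
                                 seed = seed)[[1]]
  tilt <- matrix(rep(seq(0, 30, length.out = spec$n_rows), spec$n_cols),
                 spec$n_rows, spec$n_cols)
  100 + 40 * g + tilt
}

#' Run the full mapping workflow
#'
#' Simulates the landscape and plots, builds the environmental and spectral
#' covariate stacks, delineates the study area, evaluates the composite
#' model per species under nested cross-validation, predicts rasters for
#' the first species, scores categorical baselines on shared partitions,
#' and writes region/interval summaries. All artifacts land in
#' `config$out_dir` together with a checksum manifest.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory results (`plots`, `stack`,
#'   `study_area`, `evaluations`, `raster`, `comparison`, `areas`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- grid_spec(config$n_rows, config$n_cols)

  say("simulate: landscape + plots")
  presets <- make_species_presets()[config$species]
  truth <- simulate_landscape(spec, presets, n_gradients = 2,
                              correlation_length_cells =
                                config$correlation_length_cells,
                              seed = derive_seed(config$master_seed,
                                                 "landscape"))
  design <- sampling_design(config$n_plots, "stratified_random",
                            seed = derive_seed(config$master_seed, "plots"))
  plots <- sample_plots(truth, design)
  write_plot_table(plots, file.path(config$out_dir, "plots.csv"))

  say("covariates: terrain + hydro + spectral")
  dem <- synthesize_dem(spec, derive_seed(config$master_seed, "dem"))
  climate_names <- c("date_of_freeze", "date_of_thaw",
                     "growing_season_length", "summer_warmth_index",
                     "annual_precipitation")
  climate <- generate_latent_gradients(spec, length(climate_names), 12,
                                       derive_seed(config$master_seed,
                                                   "climate"))
  names(climate) <- climate_names
  env <- build_environmental_stack(dem, spec,
                                   latitude_deg = config$latitude_deg,
                                   climate_layers = climate)
  composites <- lapply(spectral_months(), function(m) {
    scenes <- simulate_scenes(truth$gradients, spec, m,
                              seed = derive_seed(config$master_seed,
                                                 "scenes"))
    impute_gaps(max_ndvi_composite(scenes, config$evi2_formula), spec)
  })
  stack <- c(env, build_spectral_stack(composites))

  say("study area")
  idx <- cbind(plots$row, plots$col)
  site_rows <- !duplicated(plots$site_id)
  obs_mat <- vapply(names(stack), function(nm) stack[[nm]][idx[site_rows, ,
                                                              drop = FALSE]],
                    numeric(sum(site_rows)))
  sa_cfg <- study_area_config(window_cells = min(15L, config$n_rows))
  sa <- delineate_study_area(obs_mat, stack, sa_cfg)
  write_ascii_grid(sa$mask * 1, spec,
                   file.path(config$out_dir, "study_area.asc"))

  say("train + evaluate per species (nested CV)")
  covariates <- names(stack)
  scheme <- cv_scheme(config$outer_k, config$inner_k,
                      seed = derive_seed(config$master_seed, "cv"))
  opt <- bayes_opt_config(config$n_initial_points, config$n_iterations,
                          seed = derive_seed(config$master_seed, "opt"))
  sp_clf <- hyperparameter_space("classifier", fast = config$fast_space)
  sp_reg <- hyperparameter_space("regressor", fast = config$fast_space)
  evaluations <- list()
  for (sp in names(truth$species)) {
    rows <- plots$species == sp
    dat <- plots[rows, ]
    covs <- vapply(covariates, function(nm) stack[[nm]][cbind(dat$row,
                                                              dat$col)],
                   numeric(nrow(dat)))
    dat <- cbind(dat, tibble::as_tibble(covs))
    ev <- nested_cv_evaluate(dat, covariates, scheme, opt, sp_clf, sp_reg)
    ev$report$species <- sp
    evaluations[[sp]] <- ev
  }
  report <- do.call(rbind, lapply(evaluations, `[[`, "report"))
  utils::write.csv(report, file.path(config$out_dir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE)

  say("final raster prediction (first species)")
  first <- names(truth$species)[1]
  dat1 <- plots[plots$species == first, ]
  covs1 <- vapply(covariates, function(nm) stack[[nm]][cbind(dat1$row,
                                                             dat1$col)],
                  numeric(nrow(dat1)))
  dat1 <- cbind(dat1, tibble::as_tibble(covs1))
  raster <- train_final_and_predict_raster(dat1, covariates, stack,
                                           mask = sa$mask, scheme = scheme,
                                           opt = opt,
                                           space_classifier = sp_clf,
                                           space_regressor = sp_reg)
  write_ascii_grid(raster$cover, spec,
                   file.path(config$out_dir,
                             paste0("cover_", first, ".asc")))
  write_ascii_grid(raster$distribution, spec,
                   file.path(config$out_dir,
                             paste0("distribution_", first, ".asc")))

  say("categorical baselines (shared partitions)")
  informative <- discretize_layer(truth$gradients[[1]], config$n_classes)
  random_map <- random_class_map(spec, config$n_classes,
                                 derive_seed(config$master_seed,
                                             "random_map"))
  comparison <- do.call(rbind, lapply(names(evaluations), function(sp) {
    ev <- evaluations[[sp]]
    dat <- plots[plots$species == sp, ]
    folds <- ev$predictions$fold
    r2_info <- cv_categorical_r2(informative[cbind(dat$row, dat$col)],
                                 dat$cover_pct, folds = folds)$r2
    r2_rand <- cv_categorical_r2(random_map[cbind(dat$row, dat$col)],
                                 dat$cover_pct, folds = folds)$r2
    tibble::tibble(species = sp,
                   r2_random_map = r2_rand,
                   r2_categorical_map = r2_info,
                   r2_continuous = ev$report$r2_one_to_one,
                   difference = ev$report$r2_one_to_one - r2_info)
  }))
  utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  say("area and interval summaries")
  regions <- matrix("south", spec$n_rows, spec$n_cols)
  regions[seq_len(ceiling(spec$n_rows / 2)), ] <- "north"
  areas <- area_summary(raster$cover, regions, spec)
  utils::write.csv(areas, file.path(config$out_dir, "areas.csv"),
                   row.names = FALSE, quote = FALSE)
  interval <- tryCatch(
    presence_cover_interval(raster$cover, raster$distribution),
    warning = function(w) suppressWarnings(
      presence_cover_interval(raster$cover, raster$distribution)),
    error = function(e) c(p2.5 = NA_real_, p97.5 = NA_real_))
  utils::write.csv(data.frame(species = first, p2.5 = interval[1],
                              p97.5 = interval[2]),
                   file.path(config$out_dir, "cover_interval.csv"),
                   row.names = FALSE, quote = FALSE)

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(plots = plots, stack = stack, study_area = sa,
                 evaluations = evaluations, raster = raster,
                 comparison = comparison, areas = areas,
                 manifest = manifest, spec = spec, truth = truth))
}
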