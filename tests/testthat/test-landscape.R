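test_that("latent gradients are standardized, smooth and seed-deterministic", {
  spec <- grid_spec(64, 64)
  g <- generate_latent_gradients(spec, 2, correlation_length_cells = 10,
                                 seed = 1)
  expect_length(g, 2)
  for (layer in g) {
    expect_lt(abs(mean(layer)), 0.1)
    expect_lt(abs(sd(layer) - 1), 0.1)
  }
  g2 <- generate_latent_gradients(spec, 2, 10, seed = 1)
  expect_identical(g, g2)
  # Very long correlation length: local 3x3 means carry nearly the full
  # layer variance (the field is locally constant).
  gl <- generate_latent_gradients(spec, 1, 200, seed = 2)[[1]]
  local_means <- oracle_windowed(gl, 3)
  expect_gt(sd(local_means) / sd(gl), 0.98)
  expect_error(generate_latent_gradients(spec, 1, -2, seed = 1), "positive")
})

test_that("occupancy surfaces obey the logistic link", {
  spec <- grid_spec(16, 16)
  g <- generate_latent_gradients(spec, 2, 4, seed = 3)
  flat <- species_niche("flat", occ_intercept = 0, occ_loadings = c(0, 0),
                        shared_loadings = c(0, 0), cover_max = 0.3)
  tr <- simulate_true_cover(g, flat)
  expect_true(all(tr$occupancy_prob == 0.5))
  low <- species_niche("low", occ_intercept = -30, occ_loadings = c(0, 0),
                       shared_loadings = c(0, 0), cover_max = 0.3)
  expect_lt(max(simulate_true_cover(g, low)$occupancy_prob), 1e-10)
  expect_error(
    simulate_true_cover(g[1], flat), "conform")
})

test_that("species sharing gradient loadings have correlated cover", {
  spec <- grid_spec(64, 64)
  presets <- make_species_presets()
  truth <- simulate_landscape(spec, presets, seed = 2)
  trio <- c("mesic_dominant", "mesic_shrub_a", "mesic_shrub_b")
  for (i in 1:2) for (j in (i + 1):3) {
    r <- cor(as.vector(truth$species[[trio[i]]]$expected_cover_frac),
             as.vector(truth$species[[trio[j]]]$expected_cover_frac))
    expect_gt(r, 0.8)
  }
})

test_that("line-point-intercept measurement has binomial moments", {
  # 10,000 replicate 150-point draws at true cover 0.2.
  set.seed(42)
  hits <- rbinom(10000, 150, 0.2)
  pct <- floor(100 * hits / 150 + 0.5)
  expect_lt(abs(mean(pct) - 20), 0.15)
  expect_lt(abs(sd(pct) - 100 * sqrt(0.2 * 0.8 / 150)), 0.3)
  # round-half-up contract: 30 hits of 150 is exactly 20%.
  expect_equal(floor(100 * 30 / 150 + 0.5), 20)
})

test_that("absence propagates and the trace rule zeroes sub-0.5% readings", {
  spec <- grid_spec(10, 10)
  absent <- species_niche("none", occ_intercept = -40,
                          occ_loadings = c(0, 0), shared_loadings = c(0, 0),
                          cover_max = 0.3)
  truth <- simulate_landscape(spec, list(absent), seed = 7)
  plots <- sample_plots(truth, sampling_design(50, seed = 8))
  expect_true(all(plots$cover_pct == 0))
  expect_true(all(!plots$present))
  # present flag is exactly cover_pct >= 1 everywhere
  presets <- make_species_presets()
  truth2 <- simulate_landscape(spec, presets["widespread_low"], seed = 9)
  plots2 <- sample_plots(truth2, sampling_design(80, seed = 10))
  expect_equal(plots2$present, plots2$cover_pct >= 1L)
})

test_that("plot sampling is deterministic and draws distinct cells", {
  spec <- grid_spec(20, 20)
  truth <- simulate_landscape(spec, make_species_presets()[1:2], seed = 4)
  design <- sampling_design(120, "stratified_random", seed = 5)
  p1 <- sample_plots(truth, design)
  p2 <- sample_plots(truth, design)
  expect_identical(p1, p2)
  expect_false(any(duplicated(p1$cell[!duplicated(p1$site_id)])))
  # serialized output is byte-identical across reruns
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_plot_table(p1, f1); write_plot_table(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(sample_plots(truth, sampling_design(500, seed = 1)),
               "exceeds")
})

test_that("default presets meet prevalence and dominance conditions", {
  spec <- grid_spec(64, 64)
  presets <- make_species_presets()
  expect_gte(length(presets), 4)
  truth <- simulate_landscape(spec, presets, seed = 2)
  plots <- sample_plots(truth, sampling_design(500, "stratified_random",
                                               seed = 3))
  prev <- tapply(plots$present, plots$species, mean)
  expect_lt(abs(prev[["wetland_dominant"]] - 0.58), 0.10)
  nz <- plots$cover_pct[plots$cover_pct > 0]
  expect_lt(mean(nz > 25), 0.15)
  expect_lt(mean(nz > 50), 0.03)
  # Zero inflation: zero fraction at least the mean absence rate.
  for (sp in names(truth$species)) {
    rows <- plots$species == sp
    occ <- truth$species[[sp]]$occupancy_prob[cbind(plots$row[rows],
                                                    plots$col[rows])]
    expect_gte(mean(plots$cover_pct[rows] == 0), 1 - mean(occ) - 0.07)
  }
})

test_that("measurement is mean-preserving at large n", {
  spec <- grid_spec(64, 64)
  niche <- make_species_presets()$wetland_dominant
  truth <- simulate_landscape(spec, list(niche), seed = 12)
  plots <- sample_plots(truth, sampling_design(2000, "uniform_random",
                                               seed = 13))
  idx <- cbind(plots$row, plots$col)
  true_mean <- mean(truth$species[[1]]$occupancy_prob[idx] *
                      truth$species[[1]]$expected_cover_frac[idx])
  obs_mean <- mean(plots$cover_pct) / 100
  se <- sd(plots$cover_pct / 100) / sqrt(nrow(plots))
  expect_lt(abs(obs_mean - true_mean), 2 * se + 0.005)
})

test_that("occupancy intercept calibration hits its target", {
  for (p in c(0.44, 0.58)) {
    a <- calibrate_occ_intercept(p, c(2, 0))
    got <- integrate(function(z) plogis(a + 2 * z) * dnorm(z), -8, 8)$value
    expect_lt(abs(got - p), 1e-6)
  }
})
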