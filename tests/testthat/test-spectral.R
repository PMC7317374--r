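mk_bands <- function(vals, nr = 2, nc = 2) {
  b <- lapply(vals, function(v) matrix(v, nr, nc))
  names(b) <- spectral_band_names()
  b
}

test_that("index formulas match their defining arithmetic", {
  b <- mk_bands(c(UB = 0.1, BLU = 0.1, GRE = 0.4, RED = 0.3, NI = 0.5,
                  SI1 = 0.4, SI2 = 0.2))
  expect_equal(compute_index(b, "NDVI")[1, 1], 0.25)       # (.5-.3)/(.8)
  expect_equal(compute_index(b, "NBR")[1, 1], (0.5 - 0.2) / 0.7)
  expect_equal(compute_index(b, "NDMI")[1, 1], (0.5 - 0.4) / 0.9)
  expect_equal(compute_index(b, "NDSI")[1, 1], 0)          # GRE == SI1
  expect_equal(compute_index(b, "NDWI")[1, 1], (0.4 - 0.5) / 0.9)
  expect_equal(compute_index(b, "EVI2")[1, 1],
               2.5 * (0.5 - 0.3) / (0.5 + 2.4 * 0.3 + 1))
  expect_equal(compute_index(b, "EVI2", evi2_formula = "as_printed")[1, 1],
               (0.3 - 0.4) / (0.3 + 2.4 * 0.4 + 1))
  expect_error(compute_index(b, "XYZ"), "unknown")
  # equal NI and RED: NDVI 0
  b2 <- mk_bands(c(0.1, 0.1, 0.4, 0.4, 0.4, 0.4, 0.2))
  expect_equal(compute_index(b2, "NDVI")[1, 1], 0)
})

test_that("normalized-difference indices stay within [-1, 1]", {
  spec <- grid_spec(12, 12)
  g <- generate_latent_gradients(spec, 2, 4, seed = 6)
  scenes <- simulate_scenes(g, spec, "jul", seed = 6)
  for (sc in scenes) {
    for (ix in c("NDVI", "NBR", "NDMI", "NDSI", "NDWI")) {
      v <- compute_index(sc$bands, ix)
      expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
    }
  }
})

test_that("a single cloud-free scene composites to itself", {
  spec <- grid_spec(6, 6)
  g <- generate_latent_gradients(spec, 1, 3, seed = 2)
  sc <- simulate_scenes(g, spec, "jun", years = 2015, seed = 3,
                        cloud_fraction = 0)[[1]]
  comp <- max_ndvi_composite(list(sc))
  expect_equal(comp$bands$NI, sc$bands$NI)
  expect_true(all(comp$source_year == 2015, na.rm = TRUE))
  expect_false(any(comp$gap_mask))
})

test_that("composites select the argmax-NDVI scene per pixel", {
  spec <- grid_spec(8, 8)
  g <- generate_latent_gradients(spec, 1, 3, seed = 4)
  scenes <- simulate_scenes(g, spec, "aug", years = 2013:2016, seed = 5,
                            cloud_fraction = 0.3)
  comp <- max_ndvi_composite(scenes)
  ndvis <- lapply(scenes, function(s) compute_index(s$bands, "NDVI"))
  for (r in 1:8) for (c in 1:8) {
    usable <- which(vapply(scenes,
                           function(s) !s$cloud_mask[r, c], logical(1)))
    if (length(usable) == 0) {
      expect_true(comp$gap_mask[r, c])
      next
    }
    vals <- vapply(usable, function(s) ndvis[[s]][r, c], numeric(1))
    best <- usable[which.max(vals)]
    for (bn in spectral_band_names()) {
      expect_equal(comp$bands[[bn]][r, c], scenes[[best]]$bands[[bn]][r, c])
    }
    expect_gte(comp$indices$NDVI[r, c] + 1e-12, max(vals))
  }
  # indices stay consistent with composited bands
  expect_equal(comp$indices$NBR, compute_index(comp$bands, "NBR"))
  # mixing months is refused
  other <- simulate_scenes(g, spec, "may", years = 2013, seed = 5)
  expect_error(max_ndvi_composite(c(scenes, other)), "months")
})

test_that("gap imputation copies the nearest donor and is idempotent", {
  spec <- grid_spec(5, 5)
  bands <- mk_bands(c(0.1, 0.1, 0.2, 0.3, 0.5, 0.4, 0.2), 5, 5)
  sc <- spectral_scene(bands, "jun", 2015, matrix(FALSE, 5, 5))
  comp <- max_ndvi_composite(list(sc))
  # carve a gap by hand: constant field means any donor gives v
  comp$gap_mask[3, 3] <- TRUE
  for (bn in names(comp$bands)) comp$bands[[bn]][3, 3] <- NA
  filled <- impute_gaps(comp, spec)
  expect_equal(filled$bands$NI[3, 3], 0.5)
  expect_identical(impute_gaps(filled, spec), filled)
  # random gaps equal the exhaustive nearest-donor oracle with row-major ties
  set.seed(11)
  g <- generate_latent_gradients(spec, 1, 2, seed = 12)
  sc2 <- simulate_scenes(g, spec, "jun", years = 2015, seed = 13,
                         cloud_fraction = 0)[[1]]
  comp2 <- max_ndvi_composite(list(sc2))
  gap <- matrix(runif(25) < 0.3, 5, 5)
  gap[1, 1] <- FALSE
  comp2$gap_mask <- gap
  for (bn in names(comp2$bands)) comp2$bands[[bn]][gap] <- NA
  filled2 <- impute_gaps(comp2, spec)
  for (idx in which(gap)) {
    r <- ((idx - 1) %% 5) + 1; c <- ((idx - 1) %/% 5) + 1
    best <- Inf; donor <- NA
    for (dr in 1:5) for (dc in 1:5) {
      if (gap[dr, dc]) next
      d2 <- (dr - r)^2 + (dc - c)^2
      rm_rank <- (dr - 1) * 5 + dc
      cur_rank <- if (is.na(donor)) Inf else
        (((donor - 1) %% 5)) * 5 + ((donor - 1) %/% 5) + 1
      if (d2 < best - 1e-12 || (abs(d2 - best) < 1e-12 && rm_rank < cur_rank)) {
        best <- d2; donor <- (dc - 1) * 5 + dr
      }
    }
    expect_equal(filled2$bands$NI[idx], sc2$bands$NI[donor])
  }
  # all-gap composites are unrecoverable
  comp3 <- comp2
  comp3$gap_mask <- matrix(TRUE, 5, 5)
  comp3$imputed_mask <- NULL
  expect_error(impute_gaps(comp3, spec), "impute")
})

test_that("the five-month stack has 65 named layers, 83 with environment", {
  spec <- grid_spec(10, 10)
  g <- generate_latent_gradients(spec, 2, 4, seed = 7)
  comps <- lapply(spectral_months(), function(m) {
    impute_gaps(max_ndvi_composite(simulate_scenes(g, spec, m, seed = 8)),
                spec)
  })
  stack <- build_spectral_stack(comps)
  expect_length(stack, 65)
  expect_equal(stack[["jun_ndvi"]],
               comps[[which(vapply(comps, `[[`, character(1), "month") ==
                              "jun")]]$indices$NDVI)
  expect_error(build_spectral_stack(comps[1:4]), "missing month")
  dem <- random_dem(10, 10, seed = 9) +
    matrix(rep(seq(10, 1, length.out = 10), 10), 10, 10)
  climate <- generate_latent_gradients(spec, 5, 4, seed = 10)
  names(climate) <- paste0("clim_", 1:5)
  env <- suppressWarnings(
    build_environmental_stack(dem, spec, climate_layers = climate))
  expect_length(c(env, stack), 83)
})
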