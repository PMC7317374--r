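test_that("flow accumulation follows simple chains and bowls", {
  spec5 <- grid_spec(1, 5)
  f <- d8_flow(matrix(5:1, 1, 5), spec5)
  expect_equal(as.vector(f$accumulation), 1:5)
  bowl <- matrix(2, 3, 3); bowl[2, 2] <- 1
  bowl[1, ] <- c(2.5, 2.1, 2.7); bowl[3, ] <- c(2.2, 2.4, 2.9)
  f3 <- d8_flow(bowl, grid_spec(3, 3))
  expect_equal(f3$accumulation[2, 2], 9L)
})

test_that("accumulation equals the path-walking oracle on random DEMs", {
  for (seed in 1:25) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    dem <- random_dem(nr, nc, seed = seed)
    f <- d8_flow(dem, grid_spec(nr, nc))
    want <- oracle_accumulation(as.vector(f$receiver), nr * nc)
    expect_equal(as.vector(f$accumulation), want)
    # flow conservation: outlet accumulations count every cell once
    outlets <- is.na(as.vector(f$receiver))
    expect_equal(sum(f$accumulation[outlets]), nr * nc)
    expect_true(all(f$accumulation >= 1))
  }
})

test_that("strahler order obeys the junction rules", {
  # Two order-1 tributaries joining give order 2; 1 meeting 2 stays 2.
  # Construct a Y: two headwater chains meeting at a confluence cell.
  dem <- matrix(10, 5, 3)
  dem[1, 1] <- 9; dem[2, 1] <- 8                 # west branch
  dem[1, 3] <- 9.5; dem[2, 3] <- 8.5             # east branch
  dem[3, 2] <- 7; dem[4, 2] <- 6; dem[5, 2] <- 5 # trunk
  f <- d8_flow(dem, grid_spec(5, 3))
  net <- delineate_streams(f, hydro_config(accumulation_threshold_cells = 2))
  trunk_orders <- net$strahler_order[3:5, 2]
  expect_true(all(trunk_orders == 2L))
  expect_equal(net$strahler_order[2, 1], 1L)
  expect_equal(net$strahler_order[2, 3], 1L)
})

test_that("strahler orders match the recursive oracle on random terrain", {
  for (seed in 1:20) {
    dem <- random_dem(8, 8, seed = 100 + seed) +
      matrix(rep(seq(4, 0.5, length.out = 8), 8), 8, 8)
    f <- d8_flow(dem, grid_spec(8, 8))
    net <- delineate_streams(f, hydro_config(accumulation_threshold_cells = 4))
    idx <- which(net$stream_mask)
    if (length(idx) == 0) next
    want <- oracle_strahler(as.vector(f$receiver), idx)
    expect_equal(net$strahler_order[idx], want)
    # monotone non-decreasing downstream
    rv <- as.vector(f$receiver)
    for (i in idx) {
      j <- rv[i]
      if (!is.na(j) && net$stream_mask[j]) {
        expect_gte(net$strahler_order[j], net$strahler_order[i])
      }
    }
  }
})

test_that("empty networks warn rather than fail", {
  dem <- matrix(5:1, 1, 5)
  f <- d8_flow(dem, grid_spec(1, 5))
  expect_warning(net <- delineate_streams(f, hydro_config(50)), "empty")
  expect_false(any(net$stream_mask))
})

test_that("stream distances are exact center-to-center Euclidean", {
  spec <- grid_spec(6, 6)
  net <- list(stream_mask = matrix(FALSE, 6, 6),
              strahler_order = matrix(0L, 6, 6))
  net$strahler_order[3, 3] <- 1L
  d <- distance_to_streams(net, 1:2, spec)
  expect_equal(d[3, 3], 0)
  expect_equal(d[3, 4], 30)
  expect_equal(d[4, 4], 30 * sqrt(2))
  expect_error(distance_to_streams(net, integer(0), spec), "empty")
  # random sparse network equals exhaustive oracle
  set.seed(9)
  ord <- matrix(0L, 6, 6); ord[sample(36, 5)] <- sample(1:3, 5, TRUE)
  net2 <- list(strahler_order = ord)
  for (os in list(1:2, 1:3)) {
    got <- distance_to_streams(net2, os, spec)
    mask <- ord > 0 & matrix(ord %in% os, 6, 6)
    if (any(mask)) expect_equal(got, oracle_distance(mask, spec))
  }
})

test_that("floodplain buffers scale as 10 n^2 meters", {
  cfg <- hydro_config()
  spec <- grid_spec(21, 21)
  for (n in c(1L, 3L, 5L, 9L)) {
    ord <- matrix(0L, 21, 21); ord[11, 11] <- n
    net <- list(strahler_order = ord)
    fp <- floodplain_distance(net, cfg, spec)
    radius <- 10 * n^2
    # cells whose centers are within the buffer are distance 0
    inside <- oracle_distance(ord > 0, spec) <= radius
    expect_true(all(fp[inside] == 0))
    expect_true(all(fp[!inside] > 0))
  }
  # order 1: 10 m buffer covers only the stream cell itself at 30 m
  ord <- matrix(0L, 5, 5); ord[3, 3] <- 1L
  fp1 <- floodplain_distance(list(strahler_order = ord), cfg, grid_spec(5, 5))
  expect_equal(sum(fp1 == 0), 1L)
  # union with an extra mask equals the oracle over the union
  extra <- matrix(FALSE, 5, 5); extra[1, 5] <- TRUE
  fp2 <- floodplain_distance(list(strahler_order = ord), cfg, grid_spec(5, 5),
                             extra_floodplain_mask = extra)
  u <- extra; u[3, 3] <- TRUE
  expect_equal(fp2, oracle_distance(u, grid_spec(5, 5)))
})

test_that("CTI matches its formula and responds log-linearly", {
  spec <- grid_spec(4, 4)
  flow <- list(accumulation = matrix(1, 4, 4))
  slope45 <- matrix(45, 4, 4)
  cti <- topographic_wetness(flow, slope45, spec)$compound_topographic_index
  expect_equal(cti[1, 1], log(900), tolerance = 1e-12)
  flow2 <- list(accumulation = matrix(2, 4, 4))
  cti2 <- topographic_wetness(flow2, slope45, spec)$compound_topographic_index
  expect_equal(cti2[1, 1] - cti[1, 1], log(2), tolerance = 1e-12)
  # random grid: elementwise recomputation
  set.seed(3)
  acc <- matrix(sample(1:50, 16, TRUE), 4, 4)
  sl <- matrix(runif(16, 0.5, 40), 4, 4)
  got <- topographic_wetness(list(accumulation = acc), sl,
                             spec)$compound_topographic_index
  for (i in 1:16) {
    expect_equal(got[i], log(acc[i] * 900 / tan(max(sl[i], 0.1) * pi / 180)))
  }
})

test_that("environmental stack carries the 18 expected layers", {
  spec <- grid_spec(16, 16)
  dem <- random_dem(16, 16, seed = 21) * 3 +
    matrix(rep(seq(20, 1, length.out = 16), 16), 16, 16)
  climate <- generate_latent_gradients(spec, 5, 6, seed = 22)
  names(climate) <- c("date_of_freeze", "date_of_thaw",
                      "growing_season_length", "summer_warmth_index",
                      "annual_precipitation")
  # small grid: the 50-cell stream threshold may leave an empty network
  stack <- suppressWarnings(
    build_environmental_stack(dem, spec, climate_layers = climate))
  expect_length(stack, 18)
  expect_true(all(vapply(stack, function(m) all(is.finite(m)), logical(1))))
})
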