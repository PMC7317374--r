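# D8 flow routing and stream network covariates.
#
# Routing convention: every cell points to its steepest strictly descending
# neighbor (drop divided by center distance, diagonals scaled by sqrt(2));
# ties break on a fixed clockwise-from-north neighbor order. Cells with no
# descending neighbor are closed-basin outlets — appropriate for lowland
# permafrost terrain, where closed thaw-lake basins are real hydrologic
# sinks rather than artifacts. Flats (no lower but an equal neighbor) are
# resolved by an imposed epsilon gradient toward cells that already drain;
# a fully enclosed plateau drains to its first (row-major) cell.

d8_offsets <- function() {
  cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
        dc = c(0, 1, 1, 1, 0, -1, -1, -1),
        dist = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
}

#' Hydrography configuration
#'
#' @param accumulation_threshold_cells Cells of upslope area (including self)
#'   required for a cell to be mapped as stream (default 50).
#' @param small_orders,large_orders Strahler order sets defining the small-
#'   and large-stream distance covariates.
#' @param buffer_coefficient Coefficient of the order-dependent floodplain
#'   buffer distance `d = coefficient * n^2` meters.
#' @param max_order Strahler orders are capped here (default 9).
#' @export
hydro_config <- function(accumulation_threshold_cells = 50L,
                         small_orders = c(1L, 2L),
                         large_orders = 3:9,
                         buffer_coefficient = 10,
                         max_order = 9L) {
  stopifnot(accumulation_threshold_cells >= 1,
            length(intersect(small_orders, large_orders)) == 0)
  structure(list(accumulation_threshold_cells =
                   as.integer(accumulation_threshold_cells),
                 small_orders = as.integer(small_orders),
                 large_orders = as.integer(large_orders),
                 buffer_coefficient = buffer_coefficient,
                 max_order = as.integer(max_order)),
            class = "hydro_config")
}

#' D8 flow directions and accumulation
#'
#' @param dem Elevation matrix (m).
#' @param spec A [grid_spec()].
#' @return List with `direction` (integer matrix; 1-8 = clockwise-from-north
#'   neighbor index, 0 = outlet), `accumulation` (cells draining through each
#'   cell, including itself; >= 1 everywhere) and `receiver` (linear index of
#'   the downstream cell, NA at outlets).
#' @export
d8_flow <- function(dem, spec) {
  check_layer(dem, spec)
  nr <- nrow(dem); nc <- ncol(dem)
  off <- d8_offsets()
  dirn <- matrix(NA_integer_, nr, nc)
  recv <- matrix(NA_integer_, nr, nc)
  cs <- spec$cell_size_m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      best <- 0; bk <- 0L
      for (k in 1:8) {
        rr <- r + off[k, "dr"]; ccn <- c + off[k, "dc"]
        if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
        grad <- (dem[r, c] - dem[rr, ccn]) / (off[k, "dist"] * cs)
        if (grad > best) { best <- grad; bk <- k }
      }
      if (bk > 0L) {
        dirn[r, c] <- bk
        recv[r, c] <- (c + off[bk, "dc"] - 1L) * nr + (r + off[bk, "dr"])
      } else {
        dirn[r, c] <- 0L
      }
    }
  }
  # Flat resolution: undirected cells with an equal-height neighbor drain
  # toward already-directed (or outlet) equal neighbors; enclosed plateaus
  # seed at their first row-major cell, which stays an outlet.
  repeat {
    flat <- which(dirn == 0L)
    progress <- FALSE
    for (idx in flat) {
      r <- ((idx - 1L) %% nr) + 1L; c <- ((idx - 1L) %/% nr) + 1L
      has_equal <- FALSE; target <- 0L
      for (k in 1:8) {
        rr <- r + off[k, "dr"]; ccn <- c + off[k, "dc"]
        if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
        if (dem[rr, ccn] == dem[r, c]) {
          has_equal <- TRUE
          nidx <- (ccn - 1L) * nr + rr
          drains <- dirn[rr, ccn] > 0L ||
            (dirn[rr, ccn] == 0L && !any(flat == nidx))
          # A neighbor counts as a drain target if it is directed, or is an
          # outlet that is not itself an unresolved flat.
          if (dirn[rr, ccn] > 0L) { target <- k; break }
        }
      }
      if (!has_equal) next          # strict pit: legitimate outlet
      if (target > 0L) {
        dirn[r, c] <- target
        recv[r, c] <- (c + off[target, "dc"] - 1L) * nr +
          (r + off[target, "dr"])
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  # Remaining undirected flat groups: first row-major member becomes the
  # outlet; others route toward it through equal-height neighbors by BFS.
  flat <- which(dirn == 0L)
  if (length(flat) > 0L) {
    resolved <- rep(FALSE, length(flat))
    names(resolved) <- flat
    for (seed in sort(flat)) {
      if (!is.na(recv[seed])) next
      if (dirn[seed] != 0L) next
      # BFS outward from the seed across equal-height undirected cells.
      queue <- seed
      visited <- seed
      while (length(queue) > 0L) {
        cur <- queue[1L]; queue <- queue[-1L]
        r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
        for (k in 1:8) {
          rr <- r + off[k, "dr"]; ccn <- c + off[k, "dc"]
          if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
          nidx <- (ccn - 1L) * nr + rr
          if (dem[rr, ccn] == dem[r, c] && dirn[nidx] == 0L &&
              nidx != seed && !(nidx %in% visited)) {
            # neighbor drains back toward cur (reverse of k).
            back <- ((k + 3L) %% 8L) + 1L
            dirn[nidx] <- back
            recv[nidx] <- cur
            visited <- c(visited, nidx)
            queue <- c(queue, nidx)
          }
        }
      }
    }
  }
  # Accumulation by Kahn topological order over the receiver forest.
  n <- nr * nc
  indeg <- integer(n)
  rv <- as.vector(recv)
  for (i in seq_len(n)) if (!is.na(rv[i])) indeg[rv[i]] <- indeg[rv[i]] + 1L
  acc <- rep(1L, n)
  queue <- which(indeg == 0L)
  head <- 1L
  queue <- c(queue, integer(n))   # preallocated ring
  tail <- sum(indeg == 0L)
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    j <- rv[i]
    if (!is.na(j)) {
      acc[j] <- acc[j] + acc[i]
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { tail <- tail + 1L; queue[tail] <- j }
    }
  }
  list(direction = dirn, accumulation = matrix(acc, nr, nc), receiver = recv)
}

#' Delineate a stream network with Strahler orders
#'
#' Stream cells are those whose flow accumulation meets the configured
#' threshold. Strahler order: headwater stream cells are order 1; where two
#' or more upstream tributaries of equal maximal order meet, the order
#' increments; otherwise the maximum passes through. Orders cap at
#' `config$max_order`.
#'
#' @param flow Result of [d8_flow()].
#' @param config A [hydro_config()].
#' @return List with `stream_mask` (logical matrix) and `strahler_order`
#'   (integer matrix; 0 off-stream).
#' @export
delineate_streams <- function(flow, config = hydro_config()) {
  acc <- flow$accumulation
  nr <- nrow(acc); nc <- ncol(acc)
  mask <- acc >= config$accumulation_threshold_cells
  ord <- matrix(0L, nr, nc)
  if (!any(mask)) {
    warning("no cell reaches the accumulation threshold; empty network")
    return(list(stream_mask = mask, strahler_order = ord))
  }
  rv <- as.vector(flow$receiver)
  stream_idx <- which(as.vector(mask))
  # Upstream stream neighbors per stream cell.
  ups <- vector("list", nr * nc)
  indeg <- integer(nr * nc)
  for (i in stream_idx) {
    j <- rv[i]
    if (!is.na(j) && mask[j]) {
      ups[[j]] <- c(ups[[j]], i)
      indeg[i] <- indeg[i] + 0L   # indeg counted on receivers below
    }
  }
  pending <- vapply(seq_along(ups), function(i) length(ups[[i]]), integer(1))
  ovec <- integer(nr * nc)
  queue <- stream_idx[pending[stream_idx] == 0L]
  ovec[queue] <- 1L
  done <- logical(nr * nc)
  remaining <- stream_idx
  # Process in topological order: a stream cell's order is final once all
  # upstream stream cells are ordered.
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    done[i] <- TRUE
    if (ovec[i] == 0L) {
      up_orders <- ovec[ups[[i]]]
      mx <- max(up_orders)
      ovec[i] <- if (sum(up_orders == mx) >= 2L) mx + 1L else mx
      ovec[i] <- min(ovec[i], config$max_order)
    }
    j <- rv[i]
    if (!is.na(j) && mask[j] && !done[j]) {
      if (all(done[ups[[j]]])) queue <- c(queue, j)
    }
  }
  ord[stream_idx] <- ovec[stream_idx]
  list(stream_mask = mask, strahler_order = ord)
}

# Euclidean distance (m) from every cell center to the nearest TRUE cell of a
# mask; 0 on mask cells. Exhaustive over mask cells, exact.
distance_to_mask <- function(mask, spec) {
  ctr <- cell_centers(spec)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  d2 <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in idx) {
    d2 <- pmin(d2, (ctr$x - ctr$x[i])^2 + (ctr$y - ctr$y[i])^2)
  }
  sqrt(d2)
}

#' Distance to streams of given Strahler orders
#'
#' @param network Result of [delineate_streams()].
#' @param orders Integer set of Strahler orders (e.g., `1:2` for small
#'   streams, `3:9` for large).
#' @param spec A [grid_spec()].
#' @return Matrix of Euclidean distances (m) between cell centers; 0 on
#'   stream cells of the requested orders. All-`Inf` if no such cell exists.
#' @export
distance_to_streams <- function(network, orders, spec) {
  if (length(orders) == 0L) stop("empty order subset", call. = FALSE)
  mask <- network$strahler_order %in% orders &
    matrix(TRUE, nrow(network$strahler_order), ncol(network$strahler_order))
  dim(mask) <- dim(network$strahler_order)
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  distance_to_mask(mask, spec)
}

#' Distance to the order-buffered floodplain
#'
#' Each stream cell is buffered by `d = buffer_coefficient * n^2` meters
#' (`n` = its Strahler order); the buffered network, unioned with an optional
#' extra floodplain mask, defines the floodplain. Returns Euclidean distance
#' to that union (0 inside it).
#'
#' @param network Result of [delineate_streams()].
#' @param config A [hydro_config()].
#' @param spec A [grid_spec()].
#' @param extra_floodplain_mask Optional logical matrix unioned in.
#' @return Matrix of distances (m).
#' @export
floodplain_distance <- function(network, config, spec,
                                extra_floodplain_mask = NULL) {
  ord <- network$strahler_order
  ctr <- cell_centers(spec)
  fp <- matrix(FALSE, nrow(ord), ncol(ord))
  for (i in which(ord > 0L)) {
    d <- config$buffer_coefficient * as.numeric(ord[i])^2
    fp <- fp | ((ctr$x - ctr$x[i])^2 + (ctr$y - ctr$y[i])^2 <= d^2)
  }
  if (!is.null(extra_floodplain_mask)) fp <- fp | extra_floodplain_mask
  if (!any(fp)) return(matrix(Inf, nrow(ord), ncol(ord)))
  distance_to_mask(fp, spec)
}

#' Topographic wetness layers
#'
#' Compound topographic index `CTI = ln(accumulation * cell_area /
#' tan(slope))` with a slope floor to keep the quotient finite, and an
#' integrated moisture index combining standardized shade (inverted
#' hillshade), flow-accumulation and plan-curvature terms with configurable
#' weights.
#'
#' @param flow Result of [d8_flow()].
#' @param slope_deg Slope matrix from [slope_aspect()].
#' @param spec A [grid_spec()].
#' @param dem Elevation matrix (needed for the curvature and hillshade terms
#'   of the moisture index; if `NULL`, only CTI is returned).
#' @param slope_floor_deg Minimum slope used in the CTI quotient.
#' @param imi_weights Weights for the hillshade, accumulation and curvature
#'   terms (default 0.5 / 0.35 / 0.15).
#' @return List with `compound_topographic_index` and (when `dem` is given)
#'   `integrated_moisture_index`.
#' @export
topographic_wetness <- function(flow, slope_deg, spec, dem = NULL,
                                slope_floor_deg = 0.1,
                                imi_weights = c(hillshade = 0.5,
                                                accumulation = 0.35,
                                                curvature = 0.15)) {
  acc <- flow$accumulation
  cti <- log(acc * spec$cell_area_m2 /
               tan(pmax(slope_deg, slope_floor_deg) * pi / 180))
  out <- list(compound_topographic_index = cti)
  if (!is.null(dem)) {
    sa <- slope_aspect(dem, spec)
    hs <- hillshade_layer(sa$slope_deg, sa$aspect_deg)
    curv <- curvature_layer(dem, spec)
    std <- function(m) {
      s <- stats::sd(m)
      if (s == 0) matrix(0, nrow(m), ncol(m)) else (m - mean(m)) / s
    }
    out$integrated_moisture_index <-
      imi_weights[["hillshade"]] * std(-hs) +
      imi_weights[["accumulation"]] * std(log1p(acc)) +
      imi_weights[["curvature"]] * std(curv)
  }
  out
}

# Standard analytic hillshade (sun azimuth 315 deg, altitude 45 deg).
hillshade_layer <- function(slope_deg, aspect_deg, azimuth_deg = 315,
                            altitude_deg = 45) {
  zen <- (90 - altitude_deg) * pi / 180
  az <- azimuth_deg * pi / 180
  sl <- slope_deg * pi / 180
  asp <- aspect_deg * pi / 180
  asp[aspect_deg < 0] <- 0
  hs <- cos(zen) * cos(sl) + sin(zen) * sin(sl) * cos(az - asp)
  pmax(hs, 0)
}

# Plan-agnostic concavity: 4-neighbor Laplacian (positive in hollows).
curvature_layer <- function(dem, spec) {
  p <- pad_replicate(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  (p[ri - 1L, ci] + p[ri + 1L, ci] + p[ri, ci - 1L] + p[ri, ci + 1L] -
      4 * dem) / spec$cell_size_m^2
}

#' Build the environmental covariate stack
#'
#' Terrain, hydrography and wetness layers from an elevation grid, plus any
#' provided climate-surrogate layers, as a named list of matrices.
#'
#' @param dem Elevation matrix (m).
#' @param spec A [grid_spec()].
#' @param latitude_deg Latitude for the heat load index.
#' @param config A [hydro_config()].
#' @param climate_layers Optional named list of additional layers (smooth
#'   synthetic fields standing in for gridded climate normals).
#' @return Named list of matrices (the environmental half of the model
#'   covariate stack).
#' @export
build_environmental_stack <- function(dem, spec, latitude_deg = 70,
                                      config = hydro_config(),
                                      climate_layers = NULL) {
  sa <- slope_aspect(dem, spec)
  tm <- terrain_metrics(dem, spec, latitude_deg)
  flow <- d8_flow(dem, spec)
  net <- delineate_streams(flow, config)
  wet <- topographic_wetness(flow, sa$slope_deg, spec, dem = dem)
  finite_or_large <- function(m) {
    # Covariates must be finite; an absent stream class maps to a distance
    # larger than any in-grid distance.
    lim <- sqrt((spec$n_rows^2 + spec$n_cols^2)) * spec$cell_size_m
    m[!is.finite(m)] <- lim
    m
  }
  stack <- list(
    elevation = dem,
    slope = sa$slope_deg,
    linear_aspect = linear_aspect(sa$aspect_deg),
    roughness = tm$roughness,
    heat_load_index = tm$heat_load_index,
    site_exposure = tm$site_exposure,
    surface_area_ratio = tm$surface_area_ratio,
    surface_relief_ratio = srr_fill(tm$surface_relief_ratio),
    compound_topographic_index = wet$compound_topographic_index,
    integrated_moisture_index = wet$integrated_moisture_index,
    dist_small_streams = finite_or_large(
      distance_to_streams(net, config$small_orders, spec)),
    dist_large_streams = finite_or_large(
      distance_to_streams(net, config$large_orders, spec)),
    dist_floodplain = finite_or_large(
      floodplain_distance(net, config, spec))
  )
  if (!is.null(climate_layers)) stack <- c(stack, climate_layers)
  stack
}

# Relief ratio is undefined over flat windows; 0.5 (mid-relief) is the
# neutral imputation used when stacking.
srr_fill <- function(m) { m[is.na(m)] <- 0.5; m }
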