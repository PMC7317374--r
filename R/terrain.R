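# Topographic covariates from an elevation grid. All windowed metrics use an
# odd centered window that shrinks to its valid intersection at grid edges;
# derivative-based metrics use edge-replication padding, so edge cells are
# approximations while interior cells are exact.

pad_replicate <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  p <- matrix(NA_real_, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- z
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]
  p
}

#' Slope and aspect by Horn's method
#'
#' Third-order finite differences over the 3x3 neighborhood with Horn
#' weights. Aspect is the downslope direction in degrees clockwise from
#' north in `[0, 360)`; flat cells are flagged `-1`.
#'
#' @param dem Elevation matrix (m).
#' @param spec A [grid_spec()].
#' @return List with matrices `slope_deg` and `aspect_deg`.
#' @export
slope_aspect <- function(dem, spec) {
  check_layer(dem, spec)
  if (nrow(dem) < 3L || ncol(dem) < 3L) stop("grid must be at least 3x3",
                                             call. = FALSE)
  if (all(is.na(dem))) stop("all-nodata elevation grid", call. = FALSE)
  cs <- spec$cell_size_m
  p <- pad_replicate(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  a <- p[ri - 1L, ci - 1L]; b <- p[ri - 1L, ci]; cc <- p[ri - 1L, ci + 1L]
  d <- p[ri, ci - 1L];                          f <- p[ri, ci + 1L]
  g <- p[ri + 1L, ci - 1L]; h <- p[ri + 1L, ci]; i <- p[ri + 1L, ci + 1L]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # east +
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # north +
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[dzdx == 0 & dzdy == 0] <- -1
  list(slope_deg = slope, aspect_deg = aspect)
}

#' Linear (circular mean) aspect over a moving window
#'
#' Circular mean via mean sines and cosines; flat cells (`-1`) are excluded
#' and windows containing only flat cells return `-1`.
#'
#' @param aspect_deg Aspect matrix in `[0, 360)` with `-1` for flat.
#' @param window Odd window edge length in cells.
#' @return Matrix of mean aspect in `[0, 360)` (or `-1`).
#' @export
linear_aspect <- function(aspect_deg, window = 3L) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  half <- (window - 1L) %/% 2L
  nr <- nrow(aspect_deg); nc <- ncol(aspect_deg)
  rad <- aspect_deg * pi / 180
  s <- sin(rad); co <- cos(rad)
  flat <- aspect_deg < 0
  s[flat] <- NA; co[flat] <- NA
  out <- matrix(-1, nr, nc)
  for (r in seq_len(nr)) {
    rb <- window_bounds(r, half, nr)
    for (c in seq_len(nc)) {
      cb <- window_bounds(c, half, nc)
      ws <- s[rb[1]:rb[2], cb[1]:cb[2]]
      wc <- co[rb[1]:rb[2], cb[1]:cb[2]]
      if (all(is.na(ws))) next
      ms <- mean(ws, na.rm = TRUE); mc <- mean(wc, na.rm = TRUE)
      out[r, c] <- (atan2(ms, mc) * 180 / pi) %% 360
    }
  }
  out
}

# Ruggedness: root-mean-square elevation difference between the center cell
# and its window neighbors (Riley terrain ruggedness index), or the window
# elevation range (Blaszczynski variant).
roughness_layer <- function(dem, window, method = c("riley", "blaszczynski")) {
  method <- match.arg(method)
  half <- (window - 1L) %/% 2L
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rb <- window_bounds(r, half, nr)
    for (c in seq_len(nc)) {
      cb <- window_bounds(c, half, nc)
      w <- dem[rb[1]:rb[2], cb[1]:cb[2]]
      if (method == "riley") {
        diffs <- w - dem[r, c]
        diffs <- diffs[-(which(rb[1]:rb[2] == r) +
                           (which(cb[1]:cb[2] == c) - 1L) *
                           length(rb[1]:rb[2]))]
        out[r, c] <- sqrt(mean(diffs^2))
      } else {
        out[r, c] <- max(w) - min(w)
      }
    }
  }
  out
}

# Heat load index after McCune & Keon (2002, eq. 3): aspect folded about the
# NE-SW axis so that southwest-facing slopes are warmest. Flat cells use the
# slope = 0 limit, where the aspect terms vanish.
heat_load_layer <- function(slope_deg, aspect_deg, latitude_deg) {
  l <- latitude_deg * pi / 180
  s <- slope_deg * pi / 180
  asp <- aspect_deg
  asp[asp < 0] <- 0
  folded <- abs(180 - abs(asp - 225)) * pi / 180
  exp(-1.467 + 1.582 * cos(l) * cos(s) -
        1.500 * cos(folded) * sin(s) * cos(l) -
        0.262 * sin(l) * sin(s) + 0.607 * sin(folded) * sin(s))
}

# Slope-weighted southness (site exposure): slope scaled by the cosine of the
# angular distance of aspect from due south; 0 on flat cells.
site_exposure_layer <- function(slope_deg, aspect_deg) {
  se <- slope_deg * cos((aspect_deg - 180) * pi / 180)
  se[aspect_deg < 0] <- 0
  se
}

# Surface area ratio by triangulated facets: eight triangles from the cell
# center to midpoints toward each neighbor; the ratio of true (3-D) to
# planimetric octagon area. Exactly 1/cos(slope) on an inclined plane.
surface_area_ratio_layer <- function(dem, spec) {
  cs <- spec$cell_size_m
  p <- pad_replicate(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  # Neighbor offsets in (drow, dcol), clockwise from north.
  off <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
               dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  # Planimetric midpoint positions (x east, y north) toward each neighbor.
  mx <- off[, "dc"] * cs / 2
  my <- -off[, "dr"] * cs / 2
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      zc <- p[r + 1L, c + 1L]
      zm <- vapply(1:8, function(k) {
        (zc + p[r + 1L + off[k, "dr"], c + 1L + off[k, "dc"]]) / 2
      }, numeric(1))
      a3 <- 0; a2 <- 0
      for (k in 1:8) {
        k2 <- if (k == 8L) 1L else k + 1L
        v1 <- c(mx[k], my[k], zm[k] - zc)
        v2 <- c(mx[k2], my[k2], zm[k2] - zc)
        cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
                v1[3] * v2[1] - v1[1] * v2[3],
                v1[1] * v2[2] - v1[2] * v2[1])
        a3 <- a3 + sqrt(sum(cr^2)) / 2
        a2 <- a2 + abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
      }
      out[r, c] <- a3 / a2
    }
  }
  out
}

surface_relief_ratio_layer <- function(dem, window) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rb <- window_bounds(r, half, nr)
    for (c in seq_len(nc)) {
      cb <- window_bounds(c, half, nc)
      w <- dem[rb[1]:rb[2], cb[1]:cb[2]]
      rng <- max(w) - min(w)
      if (rng > 0) out[r, c] <- (mean(w) - min(w)) / rng
    }
  }
  out
}

#' Windowed terrain metric suite
#'
#' Roughness (terrain ruggedness), heat load index, site exposure, surface
#' area ratio and surface relief ratio from an elevation grid.
#'
#' @param dem Elevation matrix (m).
#' @param spec A [grid_spec()].
#' @param latitude_deg Site latitude in degrees (for the heat load index).
#' @param window Odd window edge length (>= 3) for windowed metrics.
#' @param roughness_method `"riley"` (root-mean-square neighbor difference,
#'   default) or `"blaszczynski"` (window relief).
#' @return Named list of matrices: `roughness`, `heat_load_index`,
#'   `site_exposure`, `surface_area_ratio`, `surface_relief_ratio`.
#' @export
terrain_metrics <- function(dem, spec, latitude_deg = 70, window = 3L,
                            roughness_method = c("riley", "blaszczynski")) {
  check_layer(dem, spec)
  if (abs(latitude_deg) > 90) stop("latitude outside [-90, 90]",
                                   call. = FALSE)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3",
                                              call. = FALSE)
  roughness_method <- match.arg(roughness_method)
  sa <- slope_aspect(dem, spec)
  list(
    roughness = roughness_layer(dem, window, roughness_method),
    heat_load_index = heat_load_layer(sa$slope_deg, sa$aspect_deg,
                                      latitude_deg),
    site_exposure = site_exposure_layer(sa$slope_deg, sa$aspect_deg),
    surface_area_ratio = surface_area_ratio_layer(dem, spec),
    surface_relief_ratio = surface_relief_ratio_layer(dem, window)
  )
}
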