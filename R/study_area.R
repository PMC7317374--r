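# Statistically representative study-area delineation: a one-class boundary
# around the training covariate cloud, a moving-window proportion rule, and
# extraction of the largest contiguous qualifying region.

#' Study-area configuration
#'
#' @param bound_fraction Fraction of training observations the multivariate
#'   boundary should enclose (0.95).
#' @param window_cells Moving-window edge in cells; 50 cells = 1.5 km at
#'   30 m. Even values are adjusted up to the next odd size so the window
#'   can be centered (51 x 51 by default behaviour; set
#'   `window_anchor = "topleft"` to keep an even window anchored instead).
#' @param proportion_threshold Minimum windowed inside-proportion (0.50).
#' @param connectivity 4 (rook) or 8 (queen) for contiguity.
#' @param window_anchor `"centered"` (default) or `"topleft"`.
#' @export
study_area_config <- function(bound_fraction = 0.95, window_cells = 50L,
                              proportion_threshold = 0.50,
                              connectivity = 8L,
                              window_anchor = c("centered", "topleft")) {
  stopifnot(bound_fraction > 0, bound_fraction < 1,
            proportion_threshold > 0, proportion_threshold <= 1,
            connectivity %in% c(4L, 8L))
  window_anchor <- match.arg(window_anchor)
  window_cells <- as.integer(window_cells)
  if (window_anchor == "centered" && window_cells %% 2L == 0L) {
    window_cells <- window_cells + 1L
  }
  structure(list(bound_fraction = bound_fraction,
                 window_cells = window_cells,
                 proportion_threshold = proportion_threshold,
                 connectivity = as.integer(connectivity),
                 window_anchor = window_anchor),
            class = "study_area_config")
}

#' Fit a one-class boundary around observation covariate vectors
#'
#' A kernel one-class support-vector machine (radial basis kernel, bandwidth
#' from the median pairwise-distance heuristic, outlier fraction `nu = 1 -
#' bound_fraction`). After fitting, the decision offset is recalibrated to
#' the empirical `1 - bound_fraction` quantile of the training decision
#' values, so the training inside-fraction equals the target up to ties.
#' Covariates are standardized with training means and sds, stored for reuse
#' on rasters; constant covariates are dropped with a warning.
#'
#' @param observations Numeric matrix (rows = observations, named columns =
#'   covariates).
#' @param config A [study_area_config()].
#' @return A `novelty_boundary` with the fitted model, standardization
#'   parameters, decision offset and `inside_fraction_at_training`.
#' @export
fit_novelty_boundary <- function(observations, config = study_area_config()) {
  observations <- as.matrix(observations)
  if (nrow(observations) < 20) stop("need at least 20 observations",
                                    call. = FALSE)
  sds <- apply(observations, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(colnames(observations)[!keep], collapse = ", ")))
  }
  observations <- observations[, keep, drop = FALSE]
  mu <- colMeans(observations)
  sd_ <- apply(observations, 2, stats::sd)
  z <- scale(observations, center = mu, scale = sd_)
  # Median heuristic on a subsample cap for the RBF bandwidth.
  n <- nrow(z)
  sub <- if (n > 500) z[seq(1, n, length.out = 500), , drop = FALSE] else z
  med <- stats::median(stats::dist(sub)^2)
  gamma <- 1 / max(med, .Machine$double.eps)
  fit <- e1071::svm(z, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma,
                    nu = 1 - config$bound_fraction, scale = FALSE)
  dec <- as.numeric(attr(stats::predict(fit, z,
                                        decision.values = TRUE),
                         "decision.values"))
  offset <- stats::quantile(dec, 1 - config$bound_fraction, type = 7,
                            names = FALSE)
  inside <- mean(dec >= offset)
  structure(list(fit = fit, center = mu, scale = sd_,
                 covariates = colnames(observations), gamma = gamma,
                 offset = offset,
                 inside_fraction_at_training = inside,
                 bound_fraction = config$bound_fraction),
            class = "novelty_boundary")
}

# Decision values for new covariate rows (standardized with stored params).
boundary_decision <- function(boundary, newdata) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(boundary$covariates, colnames(newdata))
  if (length(missing) > 0) {
    stop(sprintf("missing covariate layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  z <- scale(newdata[, boundary$covariates, drop = FALSE],
             center = boundary$center, scale = boundary$scale)
  as.numeric(attr(stats::predict(boundary$fit, z, decision.values = TRUE),
                  "decision.values"))
}

#' Inside/outside decision for new observations
#'
#' @param boundary A `novelty_boundary`.
#' @param newdata Matrix or data frame with the training covariate columns.
#' @return Logical vector, `TRUE` = inside the bounding surface.
#' @export
predict_inside <- function(boundary, newdata) {
  boundary_decision(boundary, newdata) >= boundary$offset
}

#' Classify every grid cell against the boundary
#'
#' @param boundary A `novelty_boundary`.
#' @param stack Named list of covariate layers matching the training
#'   covariates by name.
#' @return Logical matrix of inside decisions.
#' @export
classify_cells <- function(boundary, stack) {
  missing <- setdiff(boundary$covariates, names(stack))
  if (length(missing) > 0) {
    stop(sprintf("missing covariate layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dims <- dim(stack[[boundary$covariates[1]]])
  X <- vapply(boundary$covariates, function(nm) as.vector(stack[[nm]]),
              numeric(prod(dims)))
  matrix(predict_inside(boundary, X), dims[1], dims[2])
}

#' Moving-window proportion of a binary layer
#'
#' Per-cell mean over a centered window, with edge windows shrunk to their
#' valid intersection. Computed with an integral image, exact.
#'
#' @param binary Logical or 0/1 matrix.
#' @param window_cells Odd window edge length.
#' @return Matrix of proportions in `[0, 1]`.
#' @export
windowed_proportion <- function(binary, window_cells) {
  b <- binary * 1
  nr <- nrow(b); nc <- ncol(b)
  if (window_cells > nr || window_cells > nc) {
    stop("window exceeds grid dimensions", call. = FALSE)
  }
  half <- (window_cells - 1L) %/% 2L
  # Summed-area table with a zero border.
  cs <- apply(b, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[2:(nr + 1L), 2:(nc + 1L)] <- cs
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    rb <- window_bounds(r, half, nr)
    for (c in seq_len(nc)) {
      cb <- window_bounds(c, half, nc)
      s <- sat[rb[2] + 1L, cb[2] + 1L] - sat[rb[1], cb[2] + 1L] -
        sat[rb[2] + 1L, cb[1]] + sat[rb[1], cb[1]]
      out[r, c] <- s / ((rb[2] - rb[1] + 1L) * (cb[2] - cb[1] + 1L))
    }
  }
  out
}

# Label connected components of a logical matrix (iterative BFS; no
# recursion so large blobs are safe). Returns an integer matrix, 0 = FALSE.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  off <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nlab <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- integer(nr * nc); queue[1L] <- start
    head <- 1L; tail <- 1L
    lab[start] <- nlab
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]; ccn <- c + off[k, 2]
        if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
        idx <- (ccn - 1L) * nr + rr
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nlab
          tail <- tail + 1L; queue[tail] <- idx
        }
      }
    }
  }
  lab
}

#' Extract the largest contiguous qualifying region
#'
#' Thresholds the windowed proportion at `proportion_threshold` (>=), labels
#' connected components under the configured connectivity, and returns the
#' component with the most cells; ties break toward the component containing
#' the smallest row-major cell index.
#'
#' @param proportion Matrix from [windowed_proportion()].
#' @param config A [study_area_config()].
#' @return A `study_area_mask`: logical `mask` (one connected component) and
#'   `component_stats` (tibble of component id, cells, area share).
#' @export
largest_contiguous_region <- function(proportion, config = study_area_config()) {
  pass <- proportion >= config$proportion_threshold
  if (!any(pass)) {
    stop(sprintf(paste0("no cell reaches proportion threshold %.2f ",
                        "(max observed %.3f)"),
                 config$proportion_threshold, max(proportion)),
         call. = FALSE)
  }
  lab <- label_components(pass, config$connectivity)
  sizes <- tabulate(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  rm_rank <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L; c <- ((idx - 1L) %/% nr) + 1L
    (r - 1L) * nc + c
  }
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    anchors <- vapply(cand, function(l) min(rm_rank(which(lab == l))),
                      numeric(1))
    cand <- cand[which.min(anchors)]
  }
  mask <- lab == cand[1L]
  stats <- tibble::tibble(component = seq_along(sizes), cells = sizes,
                          share = sizes / sum(sizes))
  structure(list(mask = mask, component_stats = stats,
                 component = cand[1L]),
            class = "study_area_mask")
}

#' Delineate the study area end to end
#'
#' Fits the one-class boundary on observation covariate vectors, classifies
#' every grid cell, applies the moving-window proportion rule and extracts
#' the largest contiguous region.
#'
#' @param observations Matrix of training covariate vectors.
#' @param stack Named list of covariate layers.
#' @param config A [study_area_config()].
#' @return A `study_area_mask` with `inside_fraction_at_training`,
#'   `inside_raster` and `proportion` attached.
#' @export
delineate_study_area <- function(observations, stack,
                                 config = study_area_config()) {
  boundary <- fit_novelty_boundary(observations, config)
  inside <- classify_cells(boundary, stack)
  w <- config$window_cells
  gmin <- min(dim(inside))
  if (w > gmin) w <- if (gmin %% 2L == 1L) gmin else gmin - 1L
  prop <- windowed_proportion(inside, w)
  res <- largest_contiguous_region(prop, config)
  res$inside_fraction_at_training <- boundary$inside_fraction_at_training
  res$inside_raster <- inside
  res$proportion <- prop
  res$boundary <- boundary
  res
}
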