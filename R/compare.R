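# Categorical-map baselines and regional summaries. A categorical map
# predicts species cover only as a per-class mean; cross-validating those
# class means with the same fold machinery as the continuous model makes
# the 1:1-line R2 values directly comparable.

#' Calibrate per-class mean cover
#'
#' Ordinary least squares on class indicators — i.e., fitted values are the
#' per-class arithmetic means of observed cover. Classes unseen at
#' prediction time fall back to the global training mean.
#'
#' @param plot_classes Class labels per observation.
#' @param observed_cover Observed cover (%) per observation.
#' @return A `class_calibration`: named vector `class_means` and scalar
#'   `global_mean`.
#' @export
calibrate_classes <- function(plot_classes, observed_cover) {
  if (length(plot_classes) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(plot_classes) == length(observed_cover))
  means <- c(tapply(observed_cover, as.character(plot_classes), mean))
  structure(list(class_means = means, global_mean = mean(observed_cover)),
            class = "class_calibration")
}

#' Predict cover from a class calibration
#'
#' @param calibration A `class_calibration`.
#' @param plot_classes Class labels to predict for.
#' @return Numeric vector of predicted mean cover.
#' @export
predict_classes <- function(calibration, plot_classes) {
  out <- calibration$class_means[as.character(plot_classes)]
  out[is.na(out)] <- calibration$global_mean
  as.numeric(out)
}

#' Cross-validated 1:1-line R2 of a categorical map
#'
#' Out-of-fold class-mean predictions merged over a single k-fold iteration
#' (each observation predicted exactly once), scored with
#' [r2_one_to_one()]. Classes absent from a training fold receive that
#' fold's global mean.
#'
#' @param plot_classes Class labels per observation.
#' @param observed_cover Observed cover per observation.
#' @param k Fold count (default 10).
#' @param seed Seed for fold assignment.
#' @param folds Optional externally supplied fold vector (to share
#'   partitions with the continuous model).
#' @return List with `r2` and the merged `predictions`.
#' @export
cv_categorical_r2 <- function(plot_classes, observed_cover, k = 10L,
                              seed = 1L, folds = NULL) {
  n <- length(observed_cover)
  if (is.null(folds)) folds <- make_folds(n, k, seed = seed)
  pred <- numeric(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    cal <- calibrate_classes(plot_classes[tr], observed_cover[tr])
    pred[folds == f] <- predict_classes(cal, plot_classes[folds == f])
  }
  list(r2 = r2_one_to_one(observed_cover, pred), predictions = pred,
       folds = folds)
}

#' Random categorical map
#'
#' Independent uniform class draw per cell — the null baseline showing that
#' cross-validated R2 of an uninformative discrete map is negative, not
#' zero.
#'
#' @param spec A [grid_spec()].
#' @param n_classes Number of classes (baseline maps use 25).
#' @param seed Integer seed.
#' @return Integer matrix of class ids in `1..n_classes`.
#' @export
random_class_map <- function(spec, n_classes = 25L, seed = 1L) {
  stopifnot(n_classes >= 2L)
  set.seed(seed)
  matrix(sample.int(n_classes, spec$n_rows * spec$n_cols, replace = TRUE),
         spec$n_rows, spec$n_cols)
}

#' Informative categorical map by discretizing a gradient
#'
#' Quantile-bins a single landscape gradient into `n_classes` classes — an
#' idealized analog of a hand-drawn vegetation map that tracks one dominant
#' environmental axis but misses the rest.
#'
#' @param layer Numeric matrix (e.g., the first latent gradient).
#' @param n_classes Number of classes.
#' @return Integer matrix of class ids.
#' @export
discretize_layer <- function(layer, n_classes = 25L) {
  q <- stats::quantile(layer, probs = seq(0, 1, length.out = n_classes + 1),
                       names = FALSE)
  q[1] <- -Inf; q[length(q)] <- Inf
  matrix(findInterval(layer, q, rightmost.closed = TRUE),
         nrow(layer), ncol(layer))
}

#' Cover-weighted vegetation area by region
#'
#' Vegetation area = sum over cells of (cover% / 100) x cell area. Also
#' reported as a percentage of region area.
#'
#' @param cover Cover raster (%, `NA` ignored).
#' @param regions Labeled raster (factor/integer/character matrix) defining
#'   regions; `NULL` summarizes the whole grid as one region.
#' @param spec A [grid_spec()].
#' @return Tibble: `region`, `cells`, `region_area_m2`, `veg_area_m2`,
#'   `veg_area_km2`, `pct_of_region`.
#' @export
area_summary <- function(cover, regions = NULL, spec) {
  if (is.null(regions)) {
    regions <- matrix("all", nrow(cover), ncol(cover))
  }
  stopifnot(identical(dim(cover), dim(regions)))
  keep <- !is.na(cover)
  reg <- as.character(regions[keep])
  cov <- cover[keep]
  ca <- spec$cell_area_m2
  agg <- tapply(cov, reg, function(v) sum(v / 100) * ca)
  cells <- tapply(cov, reg, length)
  tibble::tibble(
    region = names(agg),
    cells = as.integer(cells),
    region_area_m2 = as.numeric(cells) * ca,
    veg_area_m2 = as.numeric(agg),
    veg_area_km2 = as.numeric(agg) / 1e6,
    pct_of_region = 100 * as.numeric(agg) / (as.numeric(cells) * ca)
  )
}

#' 95% interval of predicted cover where presence is predicted
#'
#' 2.5th and 97.5th percentiles (linear interpolation between order
#' statistics, the type-7 definition) of predicted cover over cells where
#' the distribution raster predicts presence.
#'
#' @param cover Cover raster (%).
#' @param distribution Binary presence raster (1/0/`NA`).
#' @param min_presences Below this count a warning is raised and the full
#'   range is returned instead.
#' @return Named numeric vector `c(p2.5, p97.5)`.
#' @export
presence_cover_interval <- function(cover, distribution,
                                    min_presences = 40L) {
  vals <- cover[!is.na(distribution) & distribution == 1]
  if (length(vals) == 0L) stop("no predicted presences", call. = FALSE)
  if (length(vals) < min_presences) {
    warning(sprintf("only %d presence cells; returning the full range",
                    length(vals)))
    return(c(p2.5 = min(vals), p97.5 = max(vals)))
  }
  q <- stats::quantile(vals, c(0.025, 0.975), type = 7, names = FALSE)
  c(p2.5 = q[1], p97.5 = q[2])
}
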