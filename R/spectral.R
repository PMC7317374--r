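# Multi-season spectral covariates: seven top-of-atmosphere reflectance
# bands (UB, BLU, GRE, RED, NI, SI1, SI2), six derived indices, per-month
# maximum-NDVI compositing across years, and nearest-neighbor gap imputation.

#' Band, index and month vocabularies of the spectral stack
#'
#' @return Character vectors: the seven reflectance band labels, the six
#'   index labels, and the five composited months.
#' @export
spectral_band_names <- function() c("UB", "BLU", "GRE", "RED", "NI", "SI1",
                                    "SI2")

#' @rdname spectral_band_names
#' @export
spectral_index_names <- function() c("EVI2", "NBR", "NDMI", "NDSI", "NDVI",
                                     "NDWI")

#' @rdname spectral_band_names
#' @export
spectral_months <- function() c("may", "jun", "jul", "aug", "sep")

#' Construct a spectral scene
#'
#' @param bands Named list of the seven reflectance matrices (`UB`, `BLU`,
#'   `GRE`, `RED`, `NI`, `SI1`, `SI2`), unitless and >= 0 outside clouds.
#' @param month Month label (one of `"may" ... "sep"`).
#' @param year Acquisition year.
#' @param cloud_mask Logical matrix; `TRUE` marks unusable pixels.
#' @export
spectral_scene <- function(bands, month, year, cloud_mask) {
  if (!setequal(names(bands), spectral_band_names())) {
    stop("scene must carry exactly the seven reflectance bands",
         call. = FALSE)
  }
  month <- match.arg(tolower(month), spectral_months())
  structure(list(bands = bands[spectral_band_names()], month = month,
                 year = as.integer(year), cloud_mask = cloud_mask),
            class = "spectral_scene")
}

#' Compute a spectral index from reflectance bands
#'
#' Normalized-difference indices (`NDVI`, `NBR`, `NDMI`, `NDSI`, `NDWI`)
#' follow their standard two-band formulas. `EVI2` defaults to the Jiang et
#' al. (2008) two-band formulation `2.5 (NI - RED) / (NI + 2.4 RED + 1)`;
#' the alternative `(RED - GRE) / (RED + 2.4 GRE + 1)` is available via
#' `evi2_formula = "as_printed"` for comparability with sources that use it.
#' Zero denominators yield `NA`.
#'
#' @param bands Named list of band matrices.
#' @param name Index name (one of [spectral_index_names()]).
#' @param evi2_formula `"jiang2008"` (default) or `"as_printed"`.
#' @return Matrix of index values.
#' @export
compute_index <- function(bands, name,
                          evi2_formula = c("jiang2008", "as_printed")) {
  evi2_formula <- match.arg(evi2_formula)
  nd <- function(a, b) {
    den <- a + b
    out <- (a - b) / den
    out[den == 0] <- NA_real_
    out
  }
  switch(toupper(name),
    NDVI = nd(bands$NI, bands$RED),
    NBR  = nd(bands$NI, bands$SI2),
    NDMI = nd(bands$NI, bands$SI1),
    NDSI = nd(bands$GRE, bands$SI1),
    NDWI = nd(bands$GRE, bands$NI),
    EVI2 = if (evi2_formula == "jiang2008") {
      den <- bands$NI + 2.4 * bands$RED + 1
      out <- 2.5 * (bands$NI - bands$RED) / den
      out[den == 0] <- NA_real_
      out
    } else {
      den <- bands$RED + 2.4 * bands$GRE + 1
      out <- (bands$RED - bands$GRE) / den
      out[den == 0] <- NA_real_
      out
    },
    stop(sprintf("unknown index '%s'", name), call. = FALSE)
  )
}

#' Per-month maximum-NDVI composite
#'
#' Per pixel, among the scenes where the pixel is cloud-free, selects the
#' scene with the highest NDVI and copies all seven bands from it; the six
#' indices are then recomputed from the selected bands. Pixels cloudy in
#' every scene are flagged in `gap_mask` and left `NA`.
#'
#' @param scenes List of [spectral_scene()]s for one month on one grid.
#' @param evi2_formula Passed to [compute_index()].
#' @return A `monthly_composite`: `bands`, `indices`, `month`,
#'   `source_year` (matrix), `gap_mask`.
#' @export
max_ndvi_composite <- function(scenes,
                               evi2_formula = c("jiang2008", "as_printed")) {
  evi2_formula <- match.arg(evi2_formula)
  stopifnot(length(scenes) >= 1)
  months <- vapply(scenes, `[[`, character(1), "month")
  if (length(unique(months)) != 1L) stop("scenes span multiple months",
                                         call. = FALSE)
  dims <- dim(scenes[[1]]$bands$NI)
  best_ndvi <- matrix(-Inf, dims[1], dims[2])
  best_scene <- matrix(NA_integer_, dims[1], dims[2])
  for (s in seq_along(scenes)) {
    ndvi <- compute_index(scenes[[s]]$bands, "NDVI")
    usable <- !scenes[[s]]$cloud_mask & !is.na(ndvi)
    better <- usable & (ndvi > best_ndvi)
    best_ndvi[better] <- ndvi[better]
    best_scene[better] <- s
  }
  gap <- is.na(best_scene)
  bands <- lapply(spectral_band_names(), function(bn) {
    out <- matrix(NA_real_, dims[1], dims[2])
    for (s in seq_along(scenes)) {
      sel <- !gap & best_scene == s
      out[sel] <- scenes[[s]]$bands[[bn]][sel]
    }
    out
  })
  names(bands) <- spectral_band_names()
  indices <- lapply(spectral_index_names(), function(ix) {
    compute_index(bands, ix, evi2_formula)
  })
  names(indices) <- spectral_index_names()
  source_year <- matrix(NA_integer_, dims[1], dims[2])
  for (s in seq_along(scenes)) {
    sel <- !gap & best_scene == s
    source_year[sel] <- scenes[[s]]$year
  }
  structure(list(bands = bands, indices = indices, month = months[1],
                 source_year = source_year, gap_mask = gap,
                 evi2_formula = evi2_formula),
            class = "monthly_composite")
}

#' Fill composite gaps from the nearest cloud-free pixel
#'
#' Every gap pixel copies all band and index values from its nearest
#' (Euclidean, cell centers) non-gap pixel; ties break in row-major order
#' (rows scanned first within a column-major matrix means smallest linear
#' index by row, then column). The original `gap_mask` is retained for
#' provenance, so the operation is idempotent.
#'
#' @param composite A `monthly_composite`.
#' @param spec A [grid_spec()].
#' @return The composite with gaps filled and `imputed_mask` recording the
#'   pixels that were filled.
#' @export
impute_gaps <- function(composite, spec) {
  gap <- composite$gap_mask
  if (!is.null(composite$imputed_mask)) return(composite)  # already filled
  if (all(gap)) stop("all pixels are gaps; nothing to impute from",
                     call. = FALSE)
  if (!any(gap)) {
    composite$imputed_mask <- gap
    return(composite)
  }
  nr <- nrow(gap); nc <- ncol(gap)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  donor_idx <- which(!gap)
  gi <- which(gap)
  donors <- integer(length(gi))
  # Row-major rank for tie-breaking.
  rm_rank <- (rows - 1L) * nc + cols
  for (q in seq_along(gi)) {
    g <- gi[q]
    d2 <- (rows[donor_idx] - rows[g])^2 + (cols[donor_idx] - cols[g])^2
    best <- min(d2)
    cand <- donor_idx[d2 == best]
    donors[q] <- cand[which.min(rm_rank[cand])]
  }
  for (bn in names(composite$bands)) {
    composite$bands[[bn]][gi] <- composite$bands[[bn]][donors]
  }
  for (ix in names(composite$indices)) {
    composite$indices[[ix]][gi] <- composite$indices[[ix]][donors]
  }
  composite$source_year[gi] <- composite$source_year[donors]
  composite$imputed_mask <- gap
  composite
}

#' Stack five monthly composites into named covariate layers
#'
#' @param composites Named or ordered list of the five monthly composites
#'   (May through September).
#' @return Named list of 65 layers (7 bands + 6 indices per month), names
#'   like `"jun_ndvi"`, `"sep_si1"`.
#' @export
build_spectral_stack <- function(composites) {
  months <- vapply(composites, `[[`, character(1), "month")
  missing <- setdiff(spectral_months(), months)
  if (length(missing) > 0) {
    stop(sprintf("missing month(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- list()
  for (m in spectral_months()) {
    comp <- composites[[which(months == m)[1]]]
    for (bn in spectral_band_names()) {
      out[[paste0(m, "_", tolower(bn))]] <- comp$bands[[bn]]
    }
    for (ix in spectral_index_names()) {
      out[[paste0(m, "_", tolower(ix))]] <- comp$indices[[ix]]
    }
  }
  out
}

#' Simulate a year x month stack of spectral scenes
#'
#' Bands are smooth functions of a vegetation signal (a logistic blend of
#' the latent gradients scaled by a monthly phenology factor) plus per-scene
#' noise; clouds are random disks. Emulates the statistical shape of
#' top-of-atmosphere reflectance scenes, not any physical sensor model.
#'
#' @param gradients Latent gradients from [generate_latent_gradients()].
#' @param spec A [grid_spec()].
#' @param month Month label.
#' @param years Integer vector of years to simulate.
#' @param seed Integer seed.
#' @param cloud_fraction Approximate fraction of pixels cloudy per scene.
#' @return List of [spectral_scene()]s.
#' @export
simulate_scenes <- function(gradients, spec, month, years = 2013:2017,
                            seed = 1, cloud_fraction = 0.15) {
  set.seed(seed + match(tolower(month), spectral_months()))
  nr <- spec$n_rows; nc <- spec$n_cols
  phen <- c(may = 0.4, jun = 0.8, jul = 1.0, aug = 0.9, sep = 0.5)
  veg <- stats::plogis(0.8 * gradients[[1]] +
                         if (length(gradients) > 1) 0.4 * gradients[[2]] else 0)
  lapply(years, function(yr) {
    f <- phen[[tolower(month)]] * stats::runif(1, 0.9, 1.1)
    noise <- function(sd = 0.01) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    clip0 <- function(m) pmax(m, 0)
    bands <- list(
      UB  = clip0(0.08 + 0.01 * veg + noise()),
      BLU = clip0(0.09 + 0.01 * veg + noise()),
      GRE = clip0(0.10 + 0.03 * veg * f + noise()),
      RED = clip0(0.12 - 0.05 * veg * f + noise()),
      NI  = clip0(0.18 + 0.22 * veg * f + noise()),
      SI1 = clip0(0.16 - 0.04 * veg * f + noise()),
      SI2 = clip0(0.12 - 0.03 * veg * f + noise())
    )
    cloud <- matrix(FALSE, nr, nc)
    n_clouds <- stats::rpois(1, cloud_fraction * nr * nc / 28)
    if (n_clouds > 0) {
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      for (k in seq_len(n_clouds)) {
        cr <- stats::runif(1, 1, nr); ccn <- stats::runif(1, 1, nc)
        rad <- stats::runif(1, 1.5, 4)
        cloud <- cloud | ((rows - cr)^2 + (cols - ccn)^2 <= rad^2)
      }
    }
    spectral_scene(bands, month, yr, cloud)
  })
}
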