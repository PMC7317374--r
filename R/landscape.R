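#' Generate standardized smooth latent landscape gradients
#'
#' Gaussian random fields built by FFT convolution of white noise with a
#' Gaussian kernel on a torus, then standardized to mean 0, sd 1. These stand
#' in for the broad climatic and moisture gradients that structure tundra
#' vegetation; the first gradient is conventionally read as a moisture axis.
#'
#' @param spec A [grid_spec()].
#' @param n_gradients Number of independent fields.
#' @param correlation_length_cells Gaussian kernel scale in cells (> 0);
#'   larger values give smoother fields.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Named list `gradient_1 ... gradient_n` of matrices.
#' @export
generate_latent_gradients <- function(spec, n_gradients,
                                      correlation_length_cells, seed) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.finite(correlation_length_cells) || correlation_length_cells <= 0) {
    stop("correlation_length_cells must be positive", call. = FALSE)
  }
  nr <- spec$n_rows; nc <- spec$n_cols
  if (nr < 1 || nc < 1) stop("non-positive grid dimensions", call. = FALSE)
  set.seed(seed)
  # Wrapped squared-exponential kernel, normalized in the frequency domain.
  dr <- pmin(seq_len(nr) - 1L, nr - (seq_len(nr) - 1L))
  dc <- pmin(seq_len(nc) - 1L, nc - (seq_len(nc) - 1L))
  d2 <- outer(dr^2, dc^2, "+")
  kern <- exp(-d2 / (2 * correlation_length_cells^2))
  fk <- stats::fft(kern)
  out <- vector("list", n_gradients)
  for (g in seq_len(n_gradients)) {
    white <- matrix(stats::rnorm(nr * nc), nr, nc)
    sm <- Re(stats::fft(stats::fft(white) * fk, inverse = TRUE)) / (nr * nc)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    out[[g]] <- sm
  }
  names(out) <- paste0("gradient_", seq_len(n_gradients))
  out
}

#' Describe a species' niche for the simulator
#'
#' A niche couples a presence (occupancy) response and a presence-conditional
#' cover response to the latent landscape gradients. Occupancy is logistic in
#' the gradients; expected cover fraction is a saturating logistic response to
#' the shared suitability score `s = sum(shared_loadings * gradients)`, so
#' species that share loadings have correlated cover surfaces (the mechanism
#' behind the tussock-community trio).
#'
#' @param name Species label.
#' @param occ_intercept Logit-scale intercept of the occupancy response.
#' @param occ_loadings Numeric vector of logit-scale occupancy weights, one
#'   per latent gradient.
#' @param shared_loadings Weights defining the shared suitability score that
#'   drives expected cover.
#' @param cover_max Asymptotic expected cover fraction in (0, 1).
#' @param cover_steepness,cover_center Shape of the logistic cover response
#'   `cover_max * plogis(cover_steepness * (s - cover_center))`.
#' @param cover_dispersion Beta concentration (phi) of realized cover about
#'   its expectation; smaller = noisier.
#' @param microscale_sd Covariate-independent sub-grid heterogeneity added to
#'   realized cover (sd on the cover-fraction scale).
#' @return A `species_niche` object.
#' @export
species_niche <- function(name, occ_intercept, occ_loadings, shared_loadings,
                          cover_max, cover_steepness = 1, cover_center = 0,
                          cover_dispersion = 15, microscale_sd = 0.02) {
  stopifnot(cover_max > 0, cover_max < 1, cover_dispersion > 0,
            microscale_sd >= 0, length(occ_loadings) == length(shared_loadings))
  structure(
    list(name = name, occ_intercept = occ_intercept,
         occ_loadings = as.numeric(occ_loadings),
         shared_loadings = as.numeric(shared_loadings),
         cover_max = cover_max, cover_steepness = cover_steepness,
         cover_center = cover_center, cover_dispersion = cover_dispersion,
         microscale_sd = microscale_sd),
    class = "species_niche"
  )
}

#' Solve the occupancy intercept for a target prevalence
#'
#' Assuming standardized, approximately independent gradients, finds the
#' logit intercept such that mean occupancy over the landscape equals the
#' target. Uses numeric integration over the induced normal suitability
#' distribution.
#'
#' @param prevalence Target mean occupancy in (0, 1).
#' @param occ_loadings Occupancy gradient weights.
#' @return The intercept (numeric scalar).
#' @export
calibrate_occ_intercept <- function(prevalence, occ_loadings) {
  stopifnot(prevalence > 0, prevalence < 1)
  b <- sqrt(sum(occ_loadings^2))
  mean_occ <- function(a) {
    stats::integrate(function(z) stats::plogis(a + b * z) * stats::dnorm(z),
                     -8, 8)$value - prevalence
  }
  stats::uniroot(mean_occ, c(-30, 30), tol = 1e-8)$root
}

#' Species niche presets mirroring dominant arctic cover patterns
#'
#' Six presets on two latent gradients (read gradient 1 as moisture, gradient
#' 2 as a mesic/drained axis), parameterized to the observed prevalence range
#' (44-58%) and the three broad abundance patterns: a wetland sedge that is
#' frequently dominant when present; a strongly intercorrelated mesic trio
#' (tussock sedge plus two associated dwarf shrubs); a widespread species
#' rarely dominant; and a fine-scale species whose occupancy is predictable
#' but whose cover is decoupled from 30 m covariates (high microscale
#' heterogeneity), reproducing the distribution/abundance dissociation seen
#' for narrow linear-feature specialists.
#'
#' @return Named list of [species_niche()] objects: `wetland_dominant`,
#'   `mesic_dominant`, `mesic_shrub_a`, `mesic_shrub_b`, `widespread_low`,
#'   `fine_scale`.
#' @export
make_species_presets <- function() {
  preset <- function(name, prev, occ_l, shared_l, ...) {
    species_niche(name, calibrate_occ_intercept(prev, occ_l), occ_l,
                  shared_l, ...)
  }
  list(
    wetland_dominant = preset("wetland_dominant", 0.58,
      occ_l = c(2.0, 0), shared_l = c(1.5, 0),
      cover_max = 0.45, cover_steepness = 0.8, cover_center = 2.2,
      cover_dispersion = 12, microscale_sd = 0.02),
    mesic_dominant = preset("mesic_dominant", 0.45,
      occ_l = c(-0.5, 2.0), shared_l = c(-0.4, 1.6),
      cover_max = 0.45, cover_steepness = 0.8, cover_center = 2.3,
      cover_dispersion = 12, microscale_sd = 0.02),
    mesic_shrub_a = preset("mesic_shrub_a", 0.44,
      occ_l = c(-0.5, 2.0), shared_l = c(-0.4, 1.6),
      cover_max = 0.25, cover_steepness = 0.8, cover_center = 1.0,
      cover_dispersion = 15, microscale_sd = 0.02),
    mesic_shrub_b = preset("mesic_shrub_b", 0.45,
      occ_l = c(-0.5, 2.0), shared_l = c(-0.4, 1.6),
      cover_max = 0.28, cover_steepness = 0.8, cover_center = 1.1,
      cover_dispersion = 15, microscale_sd = 0.02),
    widespread_low = preset("widespread_low", 0.46,
      occ_l = c(0.8, 0.8), shared_l = c(0.6, 0.6),
      cover_max = 0.12, cover_steepness = 0.7, cover_center = 0,
      cover_dispersion = 10, microscale_sd = 0.02),
    fine_scale = preset("fine_scale", 0.45,
      occ_l = c(2.5, 1.0), shared_l = c(0, 0),
      cover_max = 0.16, cover_steepness = 0.5, cover_center = 0,
      cover_dispersion = 3, microscale_sd = 0.05)
  )
}

#' Compute a species' true occupancy and expected-cover surfaces
#'
#' @param gradients Named list of standardized gradient layers (from
#'   [generate_latent_gradients()]).
#' @param niche A [species_niche()].
#' @return List with matrices `occupancy_prob` (in `[0,1]`) and
#'   `expected_cover_frac` (in `(0,1)`), plus `suitability`.
#' @export
simulate_true_cover <- function(gradients, niche) {
  stopifnot(inherits(niche, "species_niche"))
  if (length(gradients) != length(niche$occ_loadings)) {
    stop("niche loadings and gradient count do not conform", call. = FALSE)
  }
  lin_occ <- niche$occ_intercept
  s <- 0
  for (g in seq_along(gradients)) {
    lin_occ <- lin_occ + niche$occ_loadings[g] * gradients[[g]]
    s <- s + niche$shared_loadings[g] * gradients[[g]]
  }
  if (is.numeric(s) && length(s) == 1) {
    s <- matrix(s, nrow(gradients[[1]]), ncol(gradients[[1]]))
  }
  occ <- stats::plogis(lin_occ)
  mu <- niche$cover_max *
    stats::plogis(niche$cover_steepness * (s - niche$cover_center))
  list(occupancy_prob = occ, expected_cover_frac = mu, suitability = s)
}

#' Simulate a full landscape truth object
#'
#' @param spec A [grid_spec()].
#' @param niches Named list of [species_niche()] objects.
#' @param n_gradients Number of latent gradients (must match niche loadings).
#' @param correlation_length_cells Smoothness of the gradients.
#' @param seed Integer seed.
#' @return A `landscape_truth`: `spec`, `gradients`, and per-species truth
#'   surfaces under `species`.
#' @export
simulate_landscape <- function(spec, niches, n_gradients = 2,
                               correlation_length_cells = 8, seed = 1) {
  gradients <- generate_latent_gradients(spec, n_gradients,
                                         correlation_length_cells, seed)
  species <- lapply(niches, function(n) simulate_true_cover(gradients, n))
  names(species) <- vapply(niches, `[[`, character(1), "name")
  names(niches) <- names(species)
  structure(list(spec = spec, gradients = gradients, species = species,
                 niches = niches),
            class = "landscape_truth")
}

#' Describe a plot sampling design
#'
#' A plot is one 30 m grid cell measured by line-point intercept: 150 point
#' readings (three 50-point transects) treated as independent Bernoulli draws
#' against the cell's true cover fraction. Sub-cell transect geometry is not
#' simulated because covariates are cell-level.
#'
#' @param n_plots Number of plots (distinct cells).
#' @param scheme `"stratified_random"` (quantile strata of gradient 1) or
#'   `"uniform_random"`.
#' @param points_per_plot Point readings per plot (150).
#' @param seed Integer seed.
#' @export
sampling_design <- function(n_plots, scheme = c("stratified_random",
                                                "uniform_random"),
                            points_per_plot = 150, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_plots >= 1, points_per_plot > 0)
  structure(list(n_plots = as.integer(n_plots), scheme = scheme,
                 points_per_plot = as.integer(points_per_plot),
                 seed = as.integer(seed)),
            class = "sampling_design")
}

# Pick distinct plot cells per the design scheme. Returns cell indices
# (column-major into the grid matrices).
choose_plot_cells <- function(truth, design) {
  spec <- truth$spec
  n_cells <- spec$n_rows * spec$n_cols
  if (design$n_plots > n_cells) {
    stop("n_plots exceeds the number of grid cells", call. = FALSE)
  }
  if (design$scheme == "uniform_random") {
    return(sample.int(n_cells, design$n_plots))
  }
  # Stratify on quantile bins of the first latent gradient.
  g1 <- as.vector(truth$gradients[[1]])
  n_strata <- min(10L, design$n_plots)
  strata <- cut(rank(g1, ties.method = "first"),
                breaks = n_strata, labels = FALSE)
  per <- rep(design$n_plots %/% n_strata, n_strata)
  extra <- design$n_plots %% n_strata
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  unlist(lapply(seq_len(n_strata), function(s) {
    pool <- which(strata == s)
    sample(pool, min(per[s], length(pool)))
  }), use.names = FALSE)
}

#' Sample vegetation plots from a simulated landscape
#'
#' For each plot and species: presence is Bernoulli in the cell's occupancy
#' probability; realized cover is beta-distributed about the expected cover
#' fraction (concentration `cover_dispersion`) plus microscale noise, clipped
#' to (0, 1); the 150 point readings are binomial in realized cover; percent
#' cover is the point fraction times 100 rounded half-up to an integer.
#' Measurements below 0.5% are recorded as absences (the trace rule).
#'
#' @param truth A `landscape_truth` from [simulate_landscape()].
#' @param design A [sampling_design()].
#' @return A tibble (one row per site x species) with columns `site_id`, `x`,
#'   `y`, `species`, `cover_pct` (integer 0-100), `present`, `method_tag`,
#'   plus `row`, `col` and `cell` giving the sampled grid cell.
#' @export
sample_plots <- function(truth, design) {
  stopifnot(inherits(truth, "landscape_truth"),
            inherits(design, "sampling_design"))
  set.seed(design$seed)
  spec <- truth$spec
  cells <- choose_plot_cells(truth, design)
  ctr <- cell_centers(spec)
  rows <- ((cells - 1L) %% spec$n_rows) + 1L
  cols <- ((cells - 1L) %/% spec$n_rows) + 1L
  npp <- design$points_per_plot
  species_names <- names(truth$species)
  out <- vector("list", length(species_names))
  for (si in seq_along(species_names)) {
    sp <- species_names[si]
    st <- truth$species[[sp]]
    nch <- truth$niches[[sp]]
    occ <- st$occupancy_prob[cbind(rows, cols)]
    mu <- st$expected_cover_frac[cbind(rows, cols)]
    present_true <- stats::rbinom(length(cells), 1L, occ) == 1L
    cover_pct <- integer(length(cells))
    for (i in seq_along(cells)) {
      if (present_true[i]) {
        disp <- nch$cover_dispersion %||% 15
        cf <- stats::rbeta(1, mu[i] * disp, (1 - mu[i]) * disp)
        ms <- nch$microscale_sd %||% 0
        if (ms > 0) cf <- cf + stats::rnorm(1, 0, ms)
        cf <- min(max(cf, 1e-4), 1 - 1e-4)
        hits <- stats::rbinom(1, npp, cf)
        raw <- 100 * hits / npp
        cover_pct[i] <- if (raw < 0.5) 0L else as.integer(floor(raw + 0.5))
      }
    }
    out[[si]] <- tibble::tibble(
      site_id = sprintf("site_%04d", seq_along(cells)),
      x = ctr$x[cbind(rows, cols)],
      y = ctr$y[cbind(rows, cols)],
      species = sp,
      cover_pct = cover_pct,
      present = cover_pct >= 1L,
      method_tag = "synthetic_lpi",
      row = rows, col = cols, cell = cells
    )
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a plot table as CSV
#'
#' @param plots Tibble from [sample_plots()].
#' @param path CSV path.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots[c("site_id", "x", "y", "species", "cover_pct",
                           "present", "method_tag")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$cover_pct <- as.integer(df$cover_pct)
  df$present <- as.logical(df$present)
  tibble::as_tibble(df)
}
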