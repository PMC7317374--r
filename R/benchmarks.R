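#' Benchmark plot data sets for model-recovery experiments
#'
#' Three canonical difficulty regimes used to characterize the composite
#' (hurdle) model, each with two informative smooth landscape gradients plus
#' ten pure-noise covariates on 600 plots by default:
#'
#' * `"strong_signal"`: occupancy and cover both strongly driven by the two
#'   gradients — a well-mapped dominant species. Expected behaviour: high
#'   out-of-fold AUC and substantial 1:1-line R2.
#' * `"fine_scale"`: occupancy strongly predictable but presence-conditional
#'   cover decoupled from the 30 m covariates (flat expected cover, low beta
#'   concentration, high microscale noise) — the distribution/abundance
#'   dissociation of species confined to sub-pixel linear features. Expected:
#'   high AUC, near-zero R2.
#' * `"noise"`: occupancy and cover both independent of all covariates.
#'   Expected: AUC near 0.5, R2 near or below zero.
#'
#' @param preset One of `"strong_signal"`, `"fine_scale"`, `"noise"`.
#' @param n_plots Number of plots (default 600).
#' @param seed Integer seed controlling landscape and sampling.
#' @param n_noise Number of uninformative covariates (default 10).
#' @return A tibble with `site_id`, `cover_pct`, `present` and covariate
#'   columns `cov_01 ... cov_12` (the first two informative). The niche used
#'   is attached as attribute `"niche"`.
#' @export
make_benchmark_data <- function(preset = c("strong_signal", "fine_scale",
                                           "noise"),
                                n_plots = 600, seed = 1, n_noise = 10) {
  preset <- match.arg(preset)
  niche <- switch(preset,
    strong_signal = species_niche("strong_signal",
      occ_intercept = calibrate_occ_intercept(0.5, c(2.2, 2.2)),
      occ_loadings = c(2.2, 2.2), shared_loadings = c(1.6, 1.6),
      cover_max = 0.5, cover_steepness = 0.6, cover_center = 0.5,
      cover_dispersion = 50, microscale_sd = 0.01),
    fine_scale = species_niche("fine_scale",
      occ_intercept = calibrate_occ_intercept(0.5, c(3.0, 1.2)),
      occ_loadings = c(3.0, 1.2), shared_loadings = c(0, 0),
      cover_max = 0.20, cover_steepness = 0.5, cover_center = 0,
      cover_dispersion = 8, microscale_sd = 0.05),
    noise = species_niche("noise",
      occ_intercept = 0, occ_loadings = c(0, 0), shared_loadings = c(0, 0),
      cover_max = 0.2, cover_steepness = 0.5, cover_center = 0,
      cover_dispersion = 5, microscale_sd = 0.03)
  )
  spec <- grid_spec(64, 64)
  truth <- simulate_landscape(spec, list(niche), n_gradients = 2,
                              correlation_length_cells = 8, seed = seed)
  design <- sampling_design(n_plots, "uniform_random", seed = seed + 1L)
  plots <- sample_plots(truth, design)
  idx <- cbind(plots$row, plots$col)
  covs <- data.frame(cov_01 = truth$gradients[[1]][idx],
                     cov_02 = truth$gradients[[2]][idx])
  set.seed(seed + 2L)
  for (j in seq_len(n_noise)) {
    covs[[sprintf("cov_%02d", j + 2L)]] <- stats::rnorm(nrow(plots))
  }
  out <- tibble::as_tibble(cbind(
    plots[c("site_id", "cover_pct", "present", "row", "col")], covs))
  attr(out, "niche") <- niche
  attr(out, "truth") <- truth
  out
}

#' Covariate column names of a benchmark data set
#'
#' @param data A tibble from [make_benchmark_data()].
#' @return Character vector of covariate column names.
#' @export
benchmark_covariates <- function(data) {
  grep("^cov_", names(data), value = TRUE)
}
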