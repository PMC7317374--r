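# Desk-scale boosted-tree settings used across the model tests.
fast_params <- function(role) {
  p <- list(learning_rate = 0.1, n_trees = 60L, max_depth = 3L,
            min_child_weight = 1, min_split_loss = 0,
            subsample_fraction = 0.9, column_fraction_per_tree = 1,
            column_fraction_per_level = 1, l1_penalty = 0, l2_penalty = 1)
  if (role == "classifier") p$positive_class_weight <- 1
  else p$max_delta_step <- 0
  p
}

test_that("the composite prediction gates cover on the threshold", {
  set.seed(1)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(X[, 1] > 0)
  cov <- pmax(5 + 20 * X[y == 1, 1] + rnorm(sum(y)), 1)
  clf <- train_classifier(X, y, fast_params("classifier"))
  reg <- train_regressor(X[y == 1, , drop = FALSE], cov,
                         fast_params("regressor"))
  m <- composite_model(clf, reg, threshold_tau = 0.5)
  pr <- compose_predict(m, X)
  expect_true(all(pr$cover[pr$prob < 0.5] == 0))
  expect_true(all(pr$cover[pr$prob >= 0.5] >= 0))
  expect_true(all(pr$cover <= 100))
  # boundary convention: prob exactly tau counts as presence
  expect_equal(pr$presence, pr$prob >= 0.5)
  # zero-dominance: zero predictions at least as common as sub-tau cells
  expect_gte(mean(pr$cover == 0), mean(pr$prob < 0.5))
})

test_that("classifiers separate separable data and refuse one class", {
  set.seed(2)
  X <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  clf <- train_classifier(X, y, fast_params("classifier"))
  p <- foliarmap:::predict_boosted(clf, X)
  expect_gt(auc_and_accuracy(p, y, 0.5)$auc, 0.99)
  expect_error(train_classifier(X, rep(1L, 150), fast_params("classifier")),
               "both")
})

test_that("regressors recover constants and linear signals", {
  set.seed(3)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  reg <- train_regressor(X, rep(20, 100), fast_params("regressor"))
  p <- foliarmap:::predict_boosted(reg, X)
  expect_lt(max(abs(p - 20)), 1)
  lin <- 50 + 10 * X[, 1]
  params <- fast_params("regressor"); params$n_trees <- 300L
  reg2 <- train_regressor(X, lin, params)
  p2 <- foliarmap:::predict_boosted(reg2, X)
  expect_lt(sqrt(mean((p2 - lin)^2)), 2)
  expect_error(train_regressor(X[1:3, ], rep(5, 3), fast_params("regressor")),
               "presence rows")
})

test_that("label-shuffled data gives chance-level validation AUC", {
  set.seed(4)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] > 0)
  aucs <- vapply(1:20, function(i) {
    ys <- sample(y)
    folds <- make_folds(200, 5, seed = i)
    mean(vapply(1:5, function(f) {
      m <- train_classifier(X[folds != f, ], ys[folds != f],
                            fast_params("classifier"))
      auc_and_accuracy(foliarmap:::predict_boosted(m, X[folds == f, ]),
                       ys[folds == f], 0.5)$auc
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("covariate importance is normalized and finds planted signal", {
  set.seed(5)
  X <- matrix(rnorm(1500), 500, 3, dimnames = list(NULL, c("s", "n1", "n2")))
  y <- as.integer(X[, "s"] + rnorm(500, 0, 0.3) > 0)
  clf <- train_classifier(X, y, fast_params("classifier"))
  imp <- covariate_importance(clf)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_equal(sort(imp$rank), 1:3)
  expect_equal(imp$covariate[imp$rank == 1], "s")
  expect_gt(imp$importance[imp$covariate == "s"], 0.5)
  # single-covariate model: importance 1 on its only splitter
  X1 <- X[, "s", drop = FALSE]
  imp1 <- covariate_importance(train_classifier(X1, y,
                                                fast_params("classifier")))
  expect_equal(imp1$importance, 1)
})

test_that("the planted signal is top-ranked across repeated seeds", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("s", "n1", "n2")))
    y <- 30 + 15 * X[, "s"] + rnorm(300, 0, 2)
    reg <- train_regressor(X, y, fast_params("regressor"))
    imp <- covariate_importance(reg)
    hits <- hits + (imp$covariate[imp$rank == 1] == "s")
  }
  expect_gte(hits, 18L)
})

test_that("GP optimization localizes a known 1-D optimum", {
  space <- data.frame(name = "x", type = "real", lower = 0, upper = 1,
                      log = FALSE, stringsAsFactors = FALSE)
  res <- bayes_optimize(function(p) (p$x - 0.37)^2,
                        space, bayes_opt_config(10, 20, seed = 7))
  expect_lt(abs(res$best_params$x - 0.37), 0.05)
  expect_equal(nrow(res$trace), 30)
  # degenerate budget: pure initial design
  res0 <- bayes_optimize(function(p) (p$x - 0.5)^2, space,
                         bayes_opt_config(8, 0, seed = 8))
  expect_equal(nrow(res0$trace), 8)
  expect_true(all(res0$trace$phase == "initial"))
  # determinism: identical traces under identical seeds
  res2 <- bayes_optimize(function(p) (p$x - 0.37)^2, space,
                         bayes_opt_config(10, 20, seed = 7))
  expect_identical(res$trace$objective, res2$trace$objective)
})

test_that("the hyperparameter space has exactly eleven finite dimensions", {
  for (role in c("classifier", "regressor")) {
    sp <- hyperparameter_space(role)
    expect_equal(nrow(sp), 11)
    expect_true(all(is.finite(sp$lower) & is.finite(sp$upper)))
    expect_true(all(sp$lower[sp$log] > 0))
  }
  expect_true("positive_class_weight" %in%
                hyperparameter_space("classifier")$name)
  expect_true("max_delta_step" %in% hyperparameter_space("regressor")$name)
})

test_that("nested CV predicts each observation exactly once without leakage", {
  dat <- make_benchmark_data("strong_signal", n_plots = 150, seed = 17)
  ev <- nested_cv_evaluate(dat, benchmark_covariates(dat),
                           scheme = cv_scheme(5, 4, seed = 18),
                           opt = bayes_opt_config(4, 1, seed = 19),
                           space_classifier =
                             hyperparameter_space("classifier", fast = TRUE),
                           space_regressor =
                             hyperparameter_space("regressor", fast = TRUE))
  expect_equal(nrow(ev$predictions), 150)
  expect_false(any(duplicated(ev$predictions$site_id)))
  expect_equal(sort(unique(ev$predictions$fold)), 1:5)
  expect_equal(ev$leakage_violations, 0L)
  expect_true(all(ev$taus > 0 & ev$taus < 1))
  expect_true(all(ev$predictions$predicted_cover >= 0 &
                    ev$predictions$predicted_cover <= 100))
  # rerun reproduces bit-identical merged predictions
  ev2 <- nested_cv_evaluate(dat, benchmark_covariates(dat),
                            scheme = cv_scheme(5, 4, seed = 18),
                            opt = bayes_opt_config(4, 1, seed = 19),
                            space_classifier =
                              hyperparameter_space("classifier", fast = TRUE),
                            space_regressor =
                              hyperparameter_space("regressor", fast = TRUE))
  expect_identical(ev$predictions, ev2$predictions)
})

test_that("raster prediction agrees with tabular composite prediction", {
  dat <- make_benchmark_data("strong_signal", n_plots = 120, seed = 23)
  truth <- attr(dat, "truth")
  covs <- benchmark_covariates(dat)
  stack <- c(list(cov_01 = truth$gradients[[1]],
                  cov_02 = truth$gradients[[2]]),
             lapply(3:12, function(j) matrix(0, 64, 64)))
  names(stack) <- covs
  mask <- matrix(FALSE, 64, 64); mask[1:16, 1:16] <- TRUE
  res <- train_final_and_predict_raster(
    dat, covs, stack, mask = mask,
    scheme = cv_scheme(5, 4, seed = 24),
    opt = bayes_opt_config(4, 1, seed = 25),
    space_classifier = hyperparameter_space("classifier", fast = TRUE),
    space_regressor = hyperparameter_space("regressor", fast = TRUE),
    tile_rows = 7L)
  expect_true(all(is.na(res$cover[!mask])))
  expect_true(all(!is.na(res$cover[mask])))
  # elementwise equivalence against compose_predict
  cells <- which(mask)[c(1, 50, 200)]
  Xcells <- vapply(covs, function(nm) stack[[nm]][cells], numeric(3))
  pr <- compose_predict(res$model, Xcells)
  expect_equal(res$cover[cells], pr$cover)
  expect_equal(res$distribution[cells], as.numeric(pr$presence))
  expect_error(train_final_and_predict_raster(dat, covs, stack,
                                              mask = matrix(TRUE, 2, 2)),
               "mask")
})
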