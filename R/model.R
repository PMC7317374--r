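# Composite (hurdle) species model: a probabilistic presence classifier
# gates a presence-conditional cover regressor. Both are stochastic gradient
# boosted tree ensembles tuned by Gaussian-process Bayesian optimization
# inside a nested 10-fold cross-validation; the conversion threshold tau
# balances sensitivity and specificity on pooled inner-validation
# predictions.

#' Nested cross-validation scheme
#'
#' @param outer_k,inner_k Fold counts (default 10 and 10).
#' @param seed Integer seed; all fold draws derive from it.
#' @param stratify_classifier_folds Stratify classifier folds by presence.
#' @export
cv_scheme <- function(outer_k = 10L, inner_k = 10L, seed = 1L,
                      stratify_classifier_folds = TRUE) {
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 seed = as.integer(seed),
                 stratify_classifier_folds = stratify_classifier_folds),
            class = "cv_scheme")
}

# Translate space-named hyperparameters to xgboost arguments.
xgb_params <- function(params, role) {
  base <- list(
    eta = params$learning_rate,
    max_depth = params$max_depth,
    min_child_weight = params$min_child_weight,
    gamma = params$min_split_loss,
    subsample = params$subsample_fraction,
    colsample_bytree = params$column_fraction_per_tree,
    colsample_bylevel = params$column_fraction_per_level,
    alpha = params$l1_penalty,
    lambda = params$l2_penalty,
    nthread = 1,
    verbosity = 0
  )
  if (role == "classifier") {
    base$objective <- "binary:logistic"
    base$scale_pos_weight <- params$positive_class_weight %||% 1
  } else {
    base$objective <- "reg:squarederror"
    base$max_delta_step <- params$max_delta_step %||% 0
  }
  base
}

fit_boosted <- function(X, y, params, role) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = xgb_params(params, role),
                                data = dtrain,
                                nrounds = params$n_trees, verbose = 0)
  structure(list(booster = booster, covariates = colnames(X), role = role,
                 params = params),
            class = "boosted_model")
}

predict_boosted <- function(model, X) {
  X <- as.matrix(X)
  X <- X[, model$covariates, drop = FALSE]
  stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Train the presence classifier
#'
#' Boosted trees with logistic loss emitting P(presence).
#'
#' @param X Covariate matrix or data frame (named columns).
#' @param present Binary presence labels (trace rule already applied).
#' @param params Named hyperparameter list on the
#'   [hyperparameter_space()] naming scheme.
#' @return A `boosted_model`.
#' @export
train_classifier <- function(X, present, params) {
  present <- as.integer(as.logical(present))
  if (length(unique(present)) < 2L) {
    stop("classifier needs both presence and absence rows", call. = FALSE)
  }
  fit_boosted(X, present, params, "classifier")
}

#' Train the presence-conditional cover regressor
#'
#' Squared-error boosted trees on integer percent cover (0-100 scale), fit
#' to observed presences only. Composite predictions clip to `[0, 100]`.
#'
#' @param X Covariates of presence rows.
#' @param cover_pct Integer cover (>= 1 on every row).
#' @param params Hyperparameters (see [hyperparameter_space()]).
#' @param min_rows Fail below this many presence rows (advise pooling).
#' @return A `boosted_model`.
#' @export
train_regressor <- function(X, cover_pct, params, min_rows = 10L) {
  if (length(cover_pct) < min_rows) {
    stop(sprintf(paste0("only %d presence rows; too few for inner folds - ",
                        "pool observations or reduce inner_k"),
                 length(cover_pct)), call. = FALSE)
  }
  fit_boosted(X, as.numeric(cover_pct), params, "regressor")
}

#' Assemble a composite species model
#'
#' @param classifier,regressor `boosted_model`s sharing covariate order.
#' @param threshold_tau Conversion threshold in (0, 1).
#' @param species Species label.
#' @export
composite_model <- function(classifier, regressor, threshold_tau,
                            species = "species") {
  stopifnot(threshold_tau > 0, threshold_tau < 1,
            identical(classifier$covariates, regressor$covariates))
  structure(list(classifier = classifier, regressor = regressor,
                 threshold_tau = threshold_tau,
                 covariate_names = classifier$covariates, species = species),
            class = "composite_model")
}

#' Composite cover prediction
#'
#' Where P(presence) is below tau the composite emits 0; at or above tau it
#' emits the regressor's prediction clipped to `[0, 100]`.
#'
#' @param model A [composite_model()].
#' @param X Covariate rows.
#' @return List with `cover` (percent), `prob` (presence probability) and
#'   `presence` (logical, `prob >= tau`).
#' @export
compose_predict <- function(model, X) {
  prob <- predict_boosted(model$classifier, X)
  cov <- pmin(pmax(predict_boosted(model$regressor, X), 0), 100)
  presence <- prob >= model$threshold_tau
  list(cover = ifelse(presence, cov, 0), prob = prob, presence = presence)
}

# Mean inner-validation objective for a parameter vector. role "classifier"
# returns -AUC (to minimize); "regressor" returns RMSE.
inner_cv_objective <- function(X, y, folds, role) {
  function(params) {
    vals <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; va <- folds == f
      if (role == "classifier") {
        if (length(unique(y[tr])) < 2L || length(unique(y[va])) < 2L) {
          return(NA_real_)
        }
        m <- train_classifier(X[tr, , drop = FALSE], y[tr], params)
        p <- predict_boosted(m, X[va, , drop = FALSE])
        -auc_and_accuracy(p, y[va])$auc
      } else {
        m <- fit_boosted(X[tr, , drop = FALSE], y[tr], params, "regressor")
        p <- predict_boosted(m, X[va, , drop = FALSE])
        sqrt(mean((y[va] - p)^2))
      }
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
}

#' Optimize hyperparameters by inner cross-validation
#'
#' Gaussian-process Bayesian search over the eleven-dimensional space; the
#' objective is the mean inner-validation AUC (classifier, maximized) or
#' RMSE (regressor, minimized).
#'
#' @param X Covariates (training portion only).
#' @param y Labels (binary presence) or cover values.
#' @param role `"classifier"` or `"regressor"`.
#' @param inner_k Inner fold count.
#' @param seed Seed for fold assignment.
#' @param space Hyperparameter space data frame.
#' @param opt A [bayes_opt_config()].
#' @param stratify Stratify inner folds by label (classifier default).
#' @return List with `best_params`, `best_value`, `trace` and the inner
#'   `folds` used.
#' @export
optimize_hyperparameters <- function(X, y, role, inner_k = 10L, seed = 1L,
                                     space = hyperparameter_space(role),
                                     opt = bayes_opt_config(),
                                     stratify = (role == "classifier")) {
  folds <- make_folds(length(y), inner_k, seed = seed,
                      strata = if (stratify) y else NULL)
  obj <- inner_cv_objective(X, y, folds, role)
  res <- bayes_optimize(obj, space, opt)
  res$folds <- folds
  res
}

# Pooled inner-validation classifier probabilities at given params.
pooled_inner_probs <- function(X, y, folds, params) {
  probs <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f; va <- folds == f
    m <- train_classifier(X[tr, , drop = FALSE], y[tr], params)
    probs[va] <- predict_boosted(m, X[va, , drop = FALSE])
  }
  probs
}

#' Nested cross-validated evaluation of the composite model
#'
#' For each outer fold, hyperparameters and the conversion threshold are
#' selected by inner cross-validation on the outer-training rows only; the
#' held-out fold is predicted exactly once by the resulting composite. A
#' leakage guard asserts that no outer-test row enters inner optimization.
#'
#' @param data Tibble with `present`, `cover_pct` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param scheme A [cv_scheme()].
#' @param opt A [bayes_opt_config()] used for both model roles (seeds are
#'   derived per fold and role).
#' @param space_classifier,space_regressor Hyperparameter spaces.
#' @return List: `predictions` (tibble with one row per observation:
#'   observed, predicted_prob, predicted_presence, predicted_cover, fold,
#'   tau), `report` (an evaluation report, see [evaluation_report()]),
#'   `leakage_violations` (always 0 on success) and per-fold `taus`.
#' @export
nested_cv_evaluate <- function(data, covariates, scheme = cv_scheme(),
                               opt = bayes_opt_config(),
                               space_classifier =
                                 hyperparameter_space("classifier"),
                               space_regressor =
                                 hyperparameter_space("regressor")) {
  n <- nrow(data)
  X <- as.matrix(data[covariates])
  present <- as.integer(data$present)
  cover <- as.numeric(data$cover_pct)
  if (sum(present) < scheme$outer_k || sum(1 - present) < scheme$outer_k) {
    stop("need at least outer_k presences and absences", call. = FALSE)
  }
  outer <- make_folds(n, scheme$outer_k, seed = scheme$seed,
                      strata = if (scheme$stratify_classifier_folds)
                        present else NULL)
  pred_prob <- numeric(n); pred_cover <- numeric(n)
  pred_presence <- logical(n)
  taus <- numeric(scheme$outer_k)
  leakage <- 0L
  for (f in seq_len(scheme$outer_k)) {
    tr_idx <- which(outer != f)
    te_idx <- which(outer == f)
    # Leakage guard: the rows handed to inner optimization are exactly the
    # outer-training rows; any intersection with the test fold is a defect.
    if (length(intersect(tr_idx, te_idx)) > 0L) {
      leakage <- leakage + 1L
      stop("leakage: outer-test rows entered inner optimization",
           call. = FALSE)
    }
    fold_seed <- scheme$seed + 1000L * f
    opt_f <- opt; opt_f$seed <- opt$seed + f
    oc <- optimize_hyperparameters(X[tr_idx, , drop = FALSE],
                                   present[tr_idx], "classifier",
                                   inner_k = scheme$inner_k,
                                   seed = fold_seed,
                                   space = space_classifier, opt = opt_f)
    probs_val <- pooled_inner_probs(X[tr_idx, , drop = FALSE],
                                    present[tr_idx], oc$folds,
                                    oc$best_params)
    tau <- select_threshold(probs_val, present[tr_idx])
    tau <- min(max(tau, 1e-6), 1 - 1e-6)
    pres_tr <- tr_idx[present[tr_idx] == 1L]
    orr <- optimize_hyperparameters(X[pres_tr, , drop = FALSE],
                                    cover[pres_tr], "regressor",
                                    inner_k = min(scheme$inner_k,
                                                  length(pres_tr)),
                                    seed = fold_seed + 1L,
                                    space = space_regressor, opt = opt_f)
    clf <- train_classifier(X[tr_idx, , drop = FALSE], present[tr_idx],
                            oc$best_params)
    reg <- train_regressor(X[pres_tr, , drop = FALSE], cover[pres_tr],
                           orr$best_params)
    model <- composite_model(clf, reg, tau)
    pr <- compose_predict(model, X[te_idx, , drop = FALSE])
    pred_prob[te_idx] <- pr$prob
    pred_cover[te_idx] <- pr$cover
    pred_presence[te_idx] <- pr$presence
    taus[f] <- tau
  }
  predictions <- tibble::tibble(
    site_id = if ("site_id" %in% names(data)) data$site_id else
      as.character(seq_len(n)),
    observed_cover = cover,
    observed_present = present == 1L,
    predicted_prob = pred_prob,
    predicted_presence = pred_presence,
    predicted_cover = pred_cover,
    fold = outer,
    tau = taus[outer]
  )
  report <- evaluation_report(predictions)
  list(predictions = predictions, report = report,
       leakage_violations = leakage, taus = taus)
}

#' Summarize merged out-of-fold predictions
#'
#' @param predictions Tibble as produced by [nested_cv_evaluate()].
#' @param species Optional species label carried into the report.
#' @return Tibble with one row: `r2_one_to_one`, `mae`, `rmse`, `auc`,
#'   `accuracy`, `n`.
#' @export
evaluation_report <- function(predictions, species = NA_character_) {
  em <- error_metrics(predictions$observed_cover, predictions$predicted_cover)
  aa <- auc_and_accuracy(predictions$predicted_prob,
                         predictions$observed_present, tau = NA)
  # accuracy under the per-fold taus actually applied:
  acc <- mean(predictions$predicted_presence == predictions$observed_present)
  tibble::tibble(
    species = species,
    r2_one_to_one = r2_one_to_one(predictions$observed_cover,
                                  predictions$predicted_cover),
    mae = em$mae, rmse = em$rmse,
    auc = aa$auc, accuracy = acc,
    n = nrow(predictions)
  )
}

#' Covariate importance of a boosted model
#'
#' Gain-based (size-weighted squared-error reduction) importances,
#' normalized to sum 1, with ranks. Importance values are comparable within
#' one model but not numerically across models tuned to different
#' hyperparameters.
#'
#' @param model A `boosted_model` or [composite_model()] (in which case
#'   both roles are reported).
#' @return Tibble: `covariate`, `importance`, `rank`, `role`.
#' @export
covariate_importance <- function(model) {
  one <- function(m) {
    scores <- stats::setNames(rep(0, length(m$covariates)), m$covariates)
    if (length(m$covariates) == 1L) {
      # the sole covariate does all the splitting
      scores[1L] <- 1
    } else {
      imp <- xgboost::xgb.importance(model = m$booster)
      scores[imp$Feature] <- imp$Gain
      if (sum(scores) > 0) scores <- scores / sum(scores)
    }
    tibble::tibble(covariate = names(scores),
                   importance = as.numeric(scores),
                   rank = as.integer(unname(rank(-scores,
                                                 ties.method = "first"))),
                   role = m$role)
  }
  if (inherits(model, "composite_model")) {
    rbind(one(model$classifier), one(model$regressor))
  } else {
    one(model)
  }
}

#' Train final models on all data and predict over a raster stack
#'
#' Hyperparameters and the threshold come from the same inner
#' cross-validation scheme applied to all available data; the final
#' classifier and regressor are then trained on everything. Prediction runs
#' in row tiles so memory stays bounded; cells outside the study-area mask
#' are `NA`.
#'
#' @param data Training tibble (`present`, `cover_pct`, covariates).
#' @param covariates Covariate names; each must be a layer of `stack`.
#' @param stack Named list of covariate layers.
#' @param mask Logical matrix (study area); `NULL` predicts everywhere.
#' @param scheme,opt,space_classifier,space_regressor As in
#'   [nested_cv_evaluate()].
#' @param tile_rows Rows per prediction tile.
#' @return List: `model` ([composite_model()]), `distribution` (0/1 matrix,
#'   NA outside mask), `cover` (percent matrix, NA outside mask).
#' @export
train_final_and_predict_raster <- function(data, covariates, stack,
                                           mask = NULL,
                                           scheme = cv_scheme(),
                                           opt = bayes_opt_config(),
                                           space_classifier =
                                             hyperparameter_space("classifier"),
                                           space_regressor =
                                             hyperparameter_space("regressor"),
                                           tile_rows = 64L) {
  missing <- setdiff(covariates, names(stack))
  if (length(missing) > 0) {
    stop(sprintf("stack lacks layer(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  dims <- dim(stack[[covariates[1]]])
  if (!is.null(mask) && !identical(dim(mask), dims)) {
    stop("mask grid does not match the stack", call. = FALSE)
  }
  X <- as.matrix(data[covariates])
  present <- as.integer(data$present)
  cover <- as.numeric(data$cover_pct)
  oc <- optimize_hyperparameters(X, present, "classifier",
                                 inner_k = scheme$inner_k,
                                 seed = scheme$seed,
                                 space = space_classifier, opt = opt)
  tau <- select_threshold(pooled_inner_probs(X, present, oc$folds,
                                             oc$best_params), present)
  tau <- min(max(tau, 1e-6), 1 - 1e-6)
  pres <- present == 1L
  orr <- optimize_hyperparameters(X[pres, , drop = FALSE], cover[pres],
                                  "regressor",
                                  inner_k = min(scheme$inner_k, sum(pres)),
                                  seed = scheme$seed + 1L,
                                  space = space_regressor, opt = opt)
  model <- composite_model(
    train_classifier(X, present, oc$best_params),
    train_regressor(X[pres, , drop = FALSE], cover[pres], orr$best_params),
    tau)
  distribution <- matrix(NA_real_, dims[1], dims[2])
  cover_r <- matrix(NA_real_, dims[1], dims[2])
  for (r0 in seq(1L, dims[1], by = tile_rows)) {
    r1 <- min(r0 + tile_rows - 1L, dims[1])
    rows <- r0:r1
    tile_mask <- if (is.null(mask)) matrix(TRUE, length(rows), dims[2]) else
      mask[rows, , drop = FALSE]
    if (!any(tile_mask)) next
    Xt <- vapply(covariates,
                 function(nm) as.vector(stack[[nm]][rows, , drop = FALSE]),
                 numeric(length(rows) * dims[2]))
    sel <- as.vector(tile_mask)
    pr <- compose_predict(model, Xt[sel, , drop = FALSE])
    dtile <- matrix(NA_real_, length(rows), dims[2])
    ctile <- dtile
    dtile[sel] <- as.numeric(pr$presence)
    ctile[sel] <- pr$cover
    distribution[rows, ] <- dtile
    cover_r[rows, ] <- ctile
  }
  list(model = model, distribution = distribution, cover = cover_r)
}
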