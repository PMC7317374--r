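# Gaussian-process Bayesian optimization of boosted-tree hyperparameters.
# A Matern-5/2 surrogate on the unit hypercube with expected-improvement
# acquisition; the initial design is a seeded Latin hypercube. Deliberately
# compact: the search spaces here are 11-dimensional boxes and budgets are
# tens of evaluations, so a fixed-lengthscale surrogate with a nugget is
# robust and fast.

#' The eleven-dimensional boosted-tree hyperparameter space
#'
#' Capacity, stochasticity and regularization knobs of a gradient boosted
#' tree ensemble. Ten dimensions are shared between model roles; the
#' eleventh is the positive-class weight for the presence classifier and the
#' maximum delta step for the cover regressor.
#'
#' @param role `"classifier"` or `"regressor"`.
#' @param fast If `TRUE`, narrows the tree-count range (30-80) for
#'   desk-scale experiments; the space keeps its eleven dimensions.
#' @return A data frame with columns `name`, `type` (`"real"`/`"integer"`),
#'   `lower`, `upper`, `log` (logical).
#' @export
hyperparameter_space <- function(role = c("classifier", "regressor"),
                                 fast = FALSE) {
  role <- match.arg(role)
  sp <- data.frame(
    name = c("learning_rate", "n_trees", "max_depth", "min_child_weight",
             "min_split_loss", "subsample_fraction",
             "column_fraction_per_tree", "column_fraction_per_level",
             "l1_penalty", "l2_penalty",
             if (role == "classifier") "positive_class_weight"
             else "max_delta_step"),
    type = c("real", "integer", "integer", "real", "real", "real", "real",
             "real", "real", "real", "real"),
    lower = c(0.02, if (fast) 30 else 50, 2, 0.5, 0, 0.5, 0.4, 0.4,
              1e-3, 1e-2, if (role == "classifier") 0.5 else 0),
    upper = c(0.3, if (fast) 80 else 250, 6, 8, 5, 1, 1, 1,
              10, 10, if (role == "classifier") 4 else 10),
    log = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
            TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(sp) == 11L)
  sp
}

#' Bayesian optimization configuration
#'
#' @param n_initial_points Size of the Latin-hypercube initial design.
#' @param n_iterations Sequential surrogate-guided evaluations after the
#'   initial design.
#' @param acquisition `"expected_improvement"` or
#'   `"lower_confidence_bound"`.
#' @param seed Integer seed.
#' @export
bayes_opt_config <- function(n_initial_points = 15L, n_iterations = 25L,
                             acquisition = c("expected_improvement",
                                             "lower_confidence_bound"),
                             seed = 1L) {
  acquisition <- match.arg(acquisition)
  stopifnot(n_initial_points >= 2L, n_iterations >= 0L)
  structure(list(n_initial_points = as.integer(n_initial_points),
                 n_iterations = as.integer(n_iterations),
                 acquisition = acquisition, seed = as.integer(seed)),
            class = "bayes_opt_config")
}

# Map unit-cube coordinates to the native space (log dims on log10 scale,
# integer dims rounded).
decode_params <- function(u, space) {
  p <- vector("list", nrow(space))
  names(p) <- space$name
  for (j in seq_len(nrow(space))) {
    lo <- space$lower[j]; hi <- space$upper[j]
    v <- if (space$log[j]) {
      10^(log10(lo) + u[j] * (log10(hi) - log10(lo)))
    } else {
      lo + u[j] * (hi - lo)
    }
    if (space$type[j] == "integer") v <- as.integer(round(v))
    p[[j]] <- v
  }
  p
}

# Matern 5/2 kernel on scaled distances.
matern52 <- function(d, lengthscale) {
  a <- sqrt(5) * d / lengthscale
  (1 + a + a^2 / 3) * exp(-a)
}

gp_fit <- function(U, y, lengthscale = 0.3, nugget = 1e-6) {
  ys <- stats::sd(y); if (ys == 0) ys <- 1
  ym <- mean(y)
  yz <- (y - ym) / ys
  D <- as.matrix(stats::dist(U))
  K <- matern52(D, lengthscale) + diag(nugget + 1e-8, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  list(U = U, L = L, alpha = alpha, ym = ym, ys = ys,
       lengthscale = lengthscale)
}

gp_predict <- function(gp, Unew) {
  Dx <- sqrt(outer(rowSums(Unew^2), rowSums(gp$U^2), "+") -
               2 * Unew %*% t(gp$U))
  Dx[!is.finite(Dx) | Dx < 0] <- 0
  Kx <- matern52(Dx, gp$lengthscale)
  mu <- as.numeric(Kx %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Kx))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$ym + gp$ys * mu, sd = gp$ys * sqrt(var))
}

#' Minimize a black-box objective with GP-guided search
#'
#' @param objective Function taking a named parameter list (decoded from the
#'   space) and returning a scalar to minimize.
#' @param space Data frame from [hyperparameter_space()] (or any frame with
#'   the same columns).
#' @param opt A [bayes_opt_config()].
#' @return List with `best_params`, `best_value` and a `trace` tibble of
#'   every evaluated point (unit coordinates, decoded values, objective).
#' @export
bayes_optimize <- function(objective, space, opt = bayes_opt_config()) {
  budget <- opt$n_initial_points + opt$n_iterations
  if (budget < opt$n_initial_points) stop("budget below initial design",
                                          call. = FALSE)
  d <- nrow(space)
  set.seed(opt$seed)
  U <- lhs::randomLHS(opt$n_initial_points, d)
  y <- numeric(0)
  evals <- list()
  for (i in seq_len(nrow(U))) {
    p <- decode_params(U[i, ], space)
    y[i] <- objective(p)
    evals[[i]] <- p
  }
  for (it in seq_len(opt$n_iterations)) {
    gp <- gp_fit(U, y)
    # Candidate pool: uniform draws plus jitter around the incumbent.
    n_cand <- 512L
    cand <- matrix(stats::runif(n_cand * d), n_cand, d)
    inc <- U[which.min(y), ]
    jit <- matrix(pmin(pmax(rep(inc, each = 64L) +
                              stats::rnorm(64L * d, 0, 0.08), 0), 1),
                  64L, d)
    cand <- rbind(cand, jit)
    pr <- gp_predict(gp, cand)
    if (opt$acquisition == "expected_improvement") {
      best <- min(y)
      z <- (best - pr$mean) / pr$sd
      acq <- (best - pr$mean) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
    } else {
      acq <- -(pr$mean - 2 * pr$sd)
    }
    pick <- which.max(acq)
    U <- rbind(U, cand[pick, ])
    p <- decode_params(cand[pick, ], space)
    y <- c(y, objective(p))
    evals[[length(y)]] <- p
  }
  best <- which.min(y)
  trace <- tibble::tibble(
    eval = seq_along(y),
    phase = rep(c("initial", "bayes"),
                c(opt$n_initial_points, length(y) - opt$n_initial_points)),
    objective = y
  )
  trace$params <- evals
  list(best_params = evals[[best]], best_value = y[best], trace = trace)
}
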