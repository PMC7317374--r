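# Performance metrics for composite cover models. The headline abundance
# metric is the 1:1-line R2 — variance explained by the identity model —
# which is unbounded below: maps that predict worse than a constant mean
# score negative.

#' 1:1-line R-squared
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`: the proportion of
#' observed variation explained by a linear model with intercept 0 and slope
#' 1. Can be negative.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return Numeric scalar.
#' @export
r2_one_to_one <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Mean absolute and root mean squared error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Named list `mae`, `rmse` (cover percentage points).
#' @export
error_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  err <- observed - predicted
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' AUC and thresholded accuracy of presence predictions
#'
#' AUC as the rank statistic: the probability that a random presence
#' outranks a random absence, ties counted one half (equivalent to the
#' Mann-Whitney U scaled by the pair count). Accuracy is the proportion
#' correct under the `prob >= tau` presence rule.
#'
#' @param probs Predicted presence probabilities.
#' @param labels Binary observed presence (0/1 or logical).
#' @param tau Conversion threshold.
#' @return Named list `auc`, `accuracy`. With a single observed class, AUC
#'   is `NA` (with a warning) and accuracy is still returned.
#' @export
auc_and_accuracy <- function(probs, labels, tau = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(probs >= tau)
  accuracy <- mean(pred == labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined with a single observed class")
    return(list(auc = NA_real_, accuracy = accuracy))
  }
  r <- rank(probs, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, accuracy = accuracy)
}

#' Deterministic k-fold partitions
#'
#' Folds differ in size by at most one. With strata, observations are dealt
#' round-robin within each stratum so per-fold class proportions stay within
#' one observation of the global proportions.
#'
#' @param n Number of observations (>= k).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strata Optional vector of stratum labels (length n).
#' @return Integer vector of fold assignments in `1..k`.
#' @export
make_folds <- function(n, k, seed = 1, strata = NULL) {
  if (n < k) stop("n must be at least k", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(strata)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    stopifnot(length(strata) == n)
    # Deal each stratum round-robin starting from a rotating offset so
    # remainders spread across folds.
    start <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- (start + length(idx)) %% k
    }
  }
  fold
}

#' Sensitivity/specificity-balancing conversion threshold
#'
#' Scans the candidate thresholds (the unique predicted probabilities plus
#' midpoints between adjacent unique values) and returns the one minimizing
#' `|sensitivity - specificity|` under the `prob >= tau` presence rule; ties
#' resolve to the smallest candidate.
#'
#' @param predicted_probs Probabilities on validation observations.
#' @param labels Binary observed presence.
#' @return The threshold tau.
#' @export
select_threshold <- function(predicted_probs, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    stop("threshold undefined: labels contain a single class", call. = FALSE)
  }
  u <- sort(unique(predicted_probs))
  cand <- u
  if (length(u) > 1L) cand <- sort(c(u, (u[-1] + u[-length(u)]) / 2))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  gap <- vapply(cand, function(t) {
    pred <- predicted_probs >= t
    sens <- sum(pred & labels == 1L) / npos
    spec <- sum(!pred & labels == 0L) / nneg
    abs(sens - spec)
  }, numeric(1))
  # Candidates whose gaps are mathematically equal can differ in the last
  # float bit; treat gaps within 1e-12 of the minimum as tied and return
  # the smallest such threshold.
  cand[gap <= min(gap) + 1e-12][1]
}
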