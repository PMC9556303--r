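#' Probability that the first control law of a pair is more beneficial
#'
#' The pair coefficient is the dot product of the classifier weights with the
#' feature difference, and the probability is its logistic transform:
#' `w_ij = W . delta`, `p_ij = 1 / (1 + exp(-w_ij))`. Because the model has no
#' intercept and the difference is antisymmetric, `p_ij + p_ji = 1` holds by
#' construction.
#'
#' @param weights An `exo_classifier` (see [train_classifier()]) or a bare
#'   numeric weight vector.
#' @param delta A `feature_delta` or bare numeric difference vector.
#' @return A `pair_evaluation` list with `pair`, `w_ij` and `p_ij`.
#' @export
pair_probability <- function(weights, delta) {
  W <- if (inherits(weights, "exo_classifier")) weights$W else weights
  d <- if (inherits(delta, "feature_delta")) delta$delta else delta
  pair <- if (inherits(delta, "feature_delta")) delta$pair else c(NA, NA)
  if (length(W) != length(d))
    stop("weight/feature length mismatch: ", length(W), " vs ", length(d),
         call. = FALSE)
  w_ij <- sum(W * d)
  list(pair = pair, w_ij = w_ij, p_ij = 1 / (1 + exp(-w_ij)))
}

#' Score and rank control laws from pairwise probabilities
#'
#' Each law's score is the sum of the probabilities of all ordered pairs in
#' which it comes first, `S_n = sum_m p_nm`; complements `p_ji = 1 - p_ij` are
#' filled in automatically, so the scores of `k` laws always sum to
#' `k (k - 1) / 2`. Laws are ranked by descending score, ties broken by law
#' index (stable).
#'
#' @param pair_probs Either a `k x k` matrix `P` with `P[i, j] = p_ij`
#'   (diagonal ignored; missing entries filled from complements), or a data
#'   frame with columns `i`, `j`, `p`.
#' @param k Number of laws (required for the data-frame form if not implied).
#' @return A `ranking_result` with `scores` and `order` (best first).
#' @examples
#' P <- matrix(NA_real_, 3, 3); P[1, 2] <- P[1, 3] <- P[2, 3] <- 0.9
#' score_laws(P)
#' @export
score_laws <- function(pair_probs, k = NULL) {
  if (is.data.frame(pair_probs)) {
    if (is.null(k)) k <- max(pair_probs$i, pair_probs$j)
    P <- matrix(NA_real_, k, k)
    P[cbind(pair_probs$i, pair_probs$j)] <- pair_probs$p
  } else {
    P <- as.matrix(pair_probs)
    k <- nrow(P)
  }
  diag(P) <- NA_real_
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && is.na(P[i, j])) {
      if (is.na(P[j, i]))
        stop("incomplete comparison: pair (", i, ",", j, ") missing", call. = FALSE)
      P[i, j] <- 1 - P[j, i]
    }
  }
  scores <- rowSums(P, na.rm = TRUE)
  structure(list(scores = scores, order = order(-scores, seq_len(k))),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("Law scores:", paste(sprintf("%.3f", x$scores), collapse = " "),
      "\nRanking (best first):", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Build labelled training pairs from conditions with measured costs
#'
#' Every ordered pair `(i, j)`, `i != j`, is emitted with its feature
#' difference and the label `1` if the first law had the lower metabolic
#' cost. Both orders of each unordered pair are included, so the dataset is
#' antisymmetric. Pairs with exactly tied costs are skipped with a warning.
#'
#' @param features List of `condition_features` (or length-64 vectors).
#' @param costs Metabolic cost per condition, W kg^-1.
#' @return A `training_pairs` object: `X` (deltas, one row per pair), `y`
#'   (labels) and `margin` (cost_i - cost_j, negative means first better).
#' @export
build_training_pairs <- function(features, costs) {
  n <- length(features)
  if (n < 2) stop("need at least 2 conditions", call. = FALSE)
  if (length(costs) != n || any(!is.finite(costs)))
    stop("costs must be finite, one per condition", call. = FALSE)
  V <- t(vapply(features,
                function(f) if (inherits(f, "condition_features")) f$vector else f,
                numeric(length(if (inherits(features[[1]], "condition_features"))
                  features[[1]]$vector else features[[1]]))))
  idx <- expand.grid(j = seq_len(n), i = seq_len(n))
  idx <- idx[idx$i != idx$j, c("i", "j")]
  margin <- costs[idx$i] - costs[idx$j]
  tied <- margin == 0
  if (any(tied)) {
    warning(sum(tied), " tied-cost pairs skipped")
    idx <- idx[!tied, ]
    margin <- margin[!tied]
  }
  X <- V[idx$i, , drop = FALSE] - V[idx$j, , drop = FALSE]
  structure(list(X = X, y = as.integer(margin < 0), margin = margin,
                 pairs = as.matrix(idx)),
            class = "training_pairs")
}

#' Train the pairwise preference classifier
#'
#' Fits a lasso-regularized logistic regression, without intercept, on
#' pairwise feature differences labelled by the sign of the metabolic-cost
#' difference. The penalty is `lambda * ||W||_1` against the summed logistic
#' log-loss (so the glmnet path value is `lambda / N`). Features are z-scored
#' internally for the L1 fit (angle bins, velocity bins and torque parameters
#' have incommensurate units) and the weights are returned on the raw feature
#' scale.
#'
#' @param pairs A `training_pairs` object, or a list with `X` and `y`.
#' @param lambda L1 penalty weight on the summed log-loss (default 1).
#' @return An `exo_classifier` with weight vector `W` aligned to the feature
#'   vector.
#' @export
train_classifier <- function(pairs, lambda = 1) {
  X <- pairs$X
  y <- pairs$y
  if (length(unique(y)) < 2)
    stop("degenerate training set: single class", call. = FALSE)
  n <- nrow(X)
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  fit <- glmnet::glmnet(scale(X, center = FALSE, scale = sds), y,
                        family = "binomial", alpha = 1,
                        lambda = lambda / n, intercept = FALSE,
                        standardize = FALSE)
  W <- as.numeric(coef(fit))[-1] / sds   # drop intercept slot, back to raw scale
  names(W) <- colnames(X)
  structure(list(W = W, lambda = lambda, n_pairs = n), class = "exo_classifier")
}

#' @export
print.exo_classifier <- function(x, ...) {
  cat(sprintf(
    "Pairwise preference classifier: %d weights (%d nonzero), lambda = %g, %d training pairs\n",
    length(x$W), sum(x$W != 0), x$lambda, x$n_pairs))
  invisible(x)
}

#' Rank a set of conditions with a trained classifier
#'
#' Computes all pairwise probabilities among the given condition feature
#' vectors and returns the probability-sum ranking.
#'
#' @param classifier An `exo_classifier`.
#' @param features List of `condition_features` (or length-64 vectors).
#' @return A `ranking_result` (see [score_laws()]).
#' @export
rank_laws <- function(classifier, features) {
  k <- length(features)
  P <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    P[i, j] <- pair_probability(classifier,
                                feature_delta(features[[i]], features[[j]]))$p_ij
  score_laws(P)
}

#' Rank laws directly by a measured objective
#'
#' Helper for the metabolic (oracle) route: lower cost is better.
#'
#' @param values Objective value per law (e.g. steady-state metabolic rate).
#' @param decreasing If TRUE larger values rank first.
#' @return A `ranking_result`.
#' @export
rank_by_value <- function(values, decreasing = FALSE) {
  if (any(!is.finite(values)))
    stop("objective values must be finite", call. = FALSE)
  s <- if (decreasing) values else -values
  structure(list(scores = s, order = order(-s, seq_along(s))),
            class = "ranking_result")
}
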