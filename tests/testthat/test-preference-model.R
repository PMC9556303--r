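test_that("pair probability is the logistic of the weight-difference dot product", {
  W <- rep(0.1, 64)
  expect_equal(pair_probability(W, rep(0, 64))$p_ij, 0.5)

  # w_ij = 2 -> logistic(2), evaluated independently
  W2 <- c(2, rep(0, 63))
  ev <- pair_probability(W2, c(1, rep(0, 63)))
  expect_equal(ev$w_ij, 2)
  expect_equal(ev$p_ij, 0.8807970779778823, tolerance = 1e-12)

  expect_error(pair_probability(W, rep(0, 10)), "mismatch")
})

test_that("complementarity p_ij + p_ji = 1 holds for arbitrary inputs", {
  set.seed(21)
  for (i in 1:50) {
    W <- rnorm(64, sd = 2)
    d <- rnorm(64, sd = 3)
    pij <- pair_probability(W, d)$p_ij
    pji <- pair_probability(W, -d)$p_ij
    expect_lt(abs(pij + pji - 1), 1e-12)
  }
})

test_that("probability-sum scoring reproduces the three-law walkthrough", {
  P <- matrix(NA_real_, 3, 3)
  P[1, 2] <- P[1, 3] <- P[2, 3] <- 0.9
  r <- score_laws(P)
  expect_equal(r$scores, c(1.8, 1.0, 0.2))
  expect_equal(r$order, c(1L, 2L, 3L))

  tie <- matrix(0.5, 3, 3)
  expect_equal(score_laws(tie)$scores, rep(1, 3))
})

test_that("scoring matches brute-force pairwise enumeration and conserves total score", {
  set.seed(33)
  for (k in 3:6) {
    P <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) P[i, j] <- runif(1)
    r <- score_laws(P)
    # independent oracle: accumulate every ordered pair explicitly
    brute <- numeric(k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      p <- if (!is.na(P[i, j])) P[i, j] else 1 - P[j, i]
      brute[i] <- brute[i] + p
    }
    expect_equal(r$scores, brute)
    expect_equal(sum(r$scores), k * (k - 1) / 2)
  }
  bad <- matrix(NA_real_, 3, 3)
  bad[1, 2] <- 0.7
  expect_error(score_laws(bad), "incomplete")
})

test_that("training pairs are labelled by metabolic-cost sign in both orders", {
  f <- lapply(c(0.3, 0.6), function(pt)
    bin_condition(make_constant_strides(2), control_law(pt, 50, 30, 10)))
  tp <- build_training_pairs(f, costs = c(3.0, 3.5))
  expect_equal(nrow(tp$X), 2)
  lab <- setNames(tp$y, paste(tp$pairs[, 1], tp$pairs[, 2]))
  expect_equal(unname(lab[c("1 2", "2 1")]), c(1L, 0L))

  f4 <- lapply(seq(0.2, 0.8, length.out = 4), function(pt)
    bin_condition(make_constant_strides(2), control_law(pt, 50, 30, 10)))
  costs <- c(3.2, 2.9, 3.8, 3.1)
  tp4 <- build_training_pairs(f4, costs)
  expect_equal(nrow(tp4$X), 4 * 3)
  for (r in seq_len(nrow(tp4$X)))   # brute-force label check
    expect_equal(tp4$y[r],
                 as.integer(costs[tp4$pairs[r, 1]] < costs[tp4$pairs[r, 2]]))

  expect_warning(tied <- build_training_pairs(f4, c(3, 3, 4, 5)), "tied")
  expect_equal(nrow(tied$X), 10)
  expect_error(build_training_pairs(f[1], 3), "at least 2")
})

test_that("lasso training recovers signs and shrinks to zero under heavy penalty", {
  set.seed(8)
  n <- 400
  X <- matrix(rnorm(n * 64), n, 64)
  colnames(X) <- paste0("f", 1:64)
  X <- rbind(X, -X)
  y <- c(as.integer(X[1:n, 1] > 0), as.integer(X[n + 1:n, 1] > 0))
  cl <- train_classifier(list(X = X, y = y))
  expect_gt(cl$W[1], 0)
  expect_gt(abs(cl$W[1]), max(abs(cl$W[-1])))

  heavy <- train_classifier(list(X = X, y = y), lambda = 1e6)
  expect_equal(unname(heavy$W), rep(0, 64))
  expect_equal(pair_probability(heavy, X[1, ])$p_ij, 0.5)

  expect_error(train_classifier(list(X = X, y = rep(1L, 2 * n))), "single class")
})

test_that("weights recovered from a known generating model agree in sign", {
  set.seed(9)
  W_true <- numeric(64)
  W_true[c(3, 10, 25, 40, 55, 62)] <- c(2, -2, 1.5, -1.5, 2, -2)
  n <- 2000
  X <- matrix(rnorm(n * 64), n, 64)
  colnames(X) <- paste0("f", 1:64)
  p <- 1 / (1 + exp(-as.numeric(X %*% W_true)))
  y <- rbinom(n, 1, p)
  X <- rbind(X, -X); y <- c(y, 1L - y)           # antisymmetric dataset
  cl <- train_classifier(list(X = X, y = y))
  active <- which(W_true != 0)
  expect_gte(mean(sign(cl$W[active]) == sign(W_true[active])), 0.9)
})

test_that("the fit matches an independent proximal-gradient solver", {
  set.seed(10)
  n <- 300; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  b_true <- c(1.5, -1, 0.5, 0, 0, 0)
  y <- rbinom(n, 1, 1 / (1 + exp(-X %*% b_true)))
  X <- rbind(X, -X); y <- c(y, 1L - y)
  N <- nrow(X)
  cl <- train_classifier(list(X = X, y = y), lambda = 5)

  # independent oracle: ISTA on the same objective (summed log-loss + 5*||b||_1
  # on sd-scaled features), weights mapped back to the raw scale
  sds <- apply(X, 2, sd)
  Xs <- scale(X, center = FALSE, scale = sds)
  lam <- 5 / N
  L <- max(eigen(crossprod(Xs) / N, symmetric = TRUE)$values) / 4
  b <- numeric(p)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in 1:4000) {
    z <- 1 / (1 + exp(-as.numeric(Xs %*% b)))
    g <- as.numeric(crossprod(Xs, z - y)) / N
    b <- soft(b - g / L, lam / L)
  }
  b_raw <- b / sds
  obj <- function(w) {
    eta <- as.numeric(X %*% w)
    sum(log(1 + exp(eta)) - y * eta) + 5 * sum(abs(w * sds))
  }
  expect_lt(abs(obj(cl$W) - obj(b_raw)) / obj(b_raw), 1e-3)
  expect_lt(max(abs(cl$W - b_raw)), 0.05)
})

test_that("rank_laws orders candidates by probability-sum score", {
  W <- numeric(64); W[61] <- 5    # prefer larger peak torque
  cl <- structure(list(W = W), class = "exo_classifier")
  feats <- lapply(c(0.2, 0.8, 0.5), function(pt)
    bin_condition(make_constant_strides(2), control_law(pt, 50, 30, 10)))
  r <- rank_laws(cl, feats)
  expect_equal(r$order, c(2L, 3L, 1L))
  expect_equal(sum(r$scores), 3)
  expect_error(rank_by_value(c(1, NA, 2)), "finite")
})
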