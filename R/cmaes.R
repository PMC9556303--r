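#' Generation size heuristic
#'
#' Number of control laws evaluated per generation,
#' `k = 4 + floor(3 ln d)` for `d` optimization parameters: 8 laws for the
#' four-parameter laboratory protocol, 6 for the two-parameter real-world
#' protocol.
#'
#' @param d Number of parameters.
#' @return Integer generation size.
#' @export
generation_size <- function(d) {
  stopifnot(d >= 1)
  as.integer(4 + floor(3 * log(d)))
}

cmaes_constants <- function(d, k) {
  mu <- floor(k / 2)
  w <- log((k + 1) / 2) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cs <- (mueff + 2) / (d + mueff + 5)
  list(
    mu = mu, weights = w, mueff = mueff, cs = cs,
    ds = 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs,
    cc = (4 + mueff / d) / (d + 4 + 2 * mueff / d),
    c1 = 2 / ((d + 1.3)^2 + mueff),
    cmu = min(1 - 2 / ((d + 1.3)^2 + mueff),
              2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff)),
    chiN = sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2)))
}

#' Initialize the CMA-ES optimizer state
#'
#' The search distribution starts at the normalized starting parameters with
#' the covariance set to the identity and the convergence parameter (step
#' size) `sigma = 0.1`, i.e. a spread of 20% of each parameter's allowable
#' range.
#'
#' @param start Starting `control_law`, or a normalized parameter vector.
#' @param bounds `parameter_bounds` defining the search space.
#' @param sigma Initial step size in normalized units.
#' @param k Generation size; defaults to [generation_size()] of `bounds$d`.
#' @return A `cmaes_state`.
#' @export
init_optimizer <- function(start = generic_law(), bounds = parameter_bounds(4),
                           sigma = 0.1, k = generation_size(bounds$d)) {
  m <- if (inherits(start, "control_law")) normalize_law(start, bounds) else start
  if (length(m) != bounds$d) stop("start has wrong dimension", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("start out of bounds", call. = FALSE)
  d <- bounds$d
  structure(list(
    mean = unname(m), C = diag(d), sigma = sigma, sigma0 = sigma,
    ps = numeric(d), pc = numeric(d), generation = 0L, d = d, k = as.integer(k),
    bounds = bounds, const = cmaes_constants(d, k), pending = NULL),
    class = "cmaes_state")
}

#' @export
print.cmaes_state <- function(x, ...) {
  cat(sprintf("CMA-ES state: d = %d, k = %d, generation %d, sigma = %.4f\n",
              x$d, x$k, x$generation, x$sigma))
  cat("mean:", paste(sprintf("%.3f", x$mean), collapse = " "), "\n")
  invisible(x)
}

#' Sample a generation of candidate control laws
#'
#' Draws `k` candidates from `Normal(mean, sigma^2 C)` in normalized space,
#' clips them to the unit box, and denormalizes them to control laws with the
#' toe-off timing constraint applied. The clipped normalized samples are
#' stored in the state as the pending plan for [cmaes_tell()].
#'
#' @param state A `cmaes_state`.
#' @param seed Optional integer seed for reproducible sampling.
#' @param toe_off,fall_min Passed to [apply_timing_constraint()].
#' @param peak_time,fall_time Fixed-parameter values used when `d = 2`.
#' @return List with elements `state` (pending plan stored), `laws` (list of
#'   `k` control laws) and `samples` (`k x d` matrix of clipped normalized
#'   parameters).
#' @export
cmaes_ask <- function(state, seed = NULL, toe_off = 62, fall_min = 10,
                      peak_time = 54.6, fall_time = 10) {
  draw <- function() {
    eg <- eigen(state$C, symmetric = TRUE)
    rt <- eg$vectors %*% diag(sqrt(pmax(eg$values, 1e-20)), state$d) %*% t(eg$vectors)
    Z <- matrix(rnorm(state$k * state$d), state$k, state$d)
    X <- sweep(Z %*% rt * state$sigma, 2, state$mean, `+`)
    pmin(pmax(X, 0), 1)
  }
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  laws <- lapply(seq_len(state$k), function(i)
    apply_timing_constraint(
      denormalize_law(X[i, ], state$bounds, peak_time = peak_time,
                      fall_time = fall_time),
      toe_off = toe_off, fall_min = fall_min))
  state$pending <- X
  list(state = state, laws = laws, samples = X)
}

#' Update the optimizer from a ranking
#'
#' Standard CMA-ES update: the new mean is the log-weighted recombination of
#' the best `floor(k/2)` candidates, and the evolution paths, covariance and
#' step size follow the standard equations. The update depends on the ranking
#' only (any strictly monotone transformation of the scores gives an
#' identical update).
#'
#' @param state A `cmaes_state` with a pending plan from [cmaes_ask()] (or
#'   with `points` supplied).
#' @param ranking A `ranking_result`, or an index vector ordering the
#'   candidates best first.
#' @param points Optional `k x d` matrix of evaluated normalized points,
#'   overriding the pending plan (used by the opportunistic optimizer).
#' @return The updated `cmaes_state`; `$mean_shift` holds the change in mean.
#' @export
cmaes_tell <- function(state, ranking, points = NULL) {
  X <- if (!is.null(points)) points else state$pending
  if (is.null(X)) stop("no pending generation: call cmaes_ask first", call. = FALSE)
  ord <- if (inherits(ranking, "ranking_result")) ranking$order else ranking
  if (length(ord) != nrow(X) || !setequal(ord, seq_len(nrow(X))))
    stop("ranking does not cover the pending plan", call. = FALSE)
  cn <- state$const
  d <- state$d
  m_old <- state$mean
  sel <- X[ord[seq_len(cn$mu)], , drop = FALSE]
  Y <- sweep(sel, 2, m_old) / state$sigma
  yw <- as.numeric(crossprod(Y, cn$weights))
  m_new <- m_old + state$sigma * yw

  eg <- eigen(state$C, symmetric = TRUE)
  Cinvsqrt <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-20)), d) %*% t(eg$vectors)
  ps <- (1 - cn$cs) * state$ps +
    sqrt(cn$cs * (2 - cn$cs) * cn$mueff) * as.numeric(Cinvsqrt %*% yw)
  g <- state$generation + 1L
  hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cn$cs)^(2 * g)) / cn$chiN <
    1.4 + 2 / (d + 1)
  pc <- (1 - cn$cc) * state$pc +
    (if (hsig) sqrt(cn$cc * (2 - cn$cc) * cn$mueff) else 0) * yw
  rank_mu <- crossprod(Y * sqrt(cn$weights))
  C <- (1 - cn$c1 - cn$cmu) * state$C +
    cn$c1 * (tcrossprod(pc) + (if (hsig) 0 else cn$cc * (2 - cn$cc)) * state$C) +
    cn$cmu * rank_mu
  C <- (C + t(C)) / 2
  sigma <- state$sigma * exp((cn$cs / cn$ds) * (sqrt(sum(ps^2)) / cn$chiN - 1))

  state$mean_shift <- m_new - m_old
  state$mean <- m_new
  state$C <- C
  state$sigma <- sigma
  state$ps <- ps
  state$pc <- pc
  state$generation <- g
  state$pending <- NULL
  state
}

#' Total walking time of an evaluation protocol
#'
#' @param generations Number of generations.
#' @param laws_per_generation Control laws per generation.
#' @param seconds_per_law Evaluation time per control law, seconds.
#' @return Total evaluation time, minutes.
#' @examples
#' protocol_duration(8, 8, 120)  # metabolic protocol: 128 min
#' protocol_duration(8, 8, 30)   # data-driven protocol: 32 min
#' @export
protocol_duration <- function(generations, laws_per_generation, seconds_per_law) {
  generations * laws_per_generation * seconds_per_law / 60
}
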