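test_that("speed bins split at 1.22 and 1.38 with a closed middle bin", {
  bins <- speed_bins()
  expect_equal(assign_bin(bins, 1.10), 1L)
  expect_equal(assign_bin(bins, 1.22), 2L)
  expect_equal(assign_bin(bins, 1.38), 2L)
  expect_equal(assign_bin(bins, 1.39), 3L)
  expect_equal(assign_bin(bins, c(1.0, 1.5)), 2L)   # mean decides
  expect_error(assign_bin(bins, numeric(0)), "at least one")
  expect_error(speed_bins(c(1.4, 1.2)), "strictly increasing")
})

test_that("the 44-step buffer completes only on continuous same-bout strides", {
  law <- generic_law()
  buf <- evaluation_buffer(law, law_id = 7L, law_norm = c(0.5, 0.5))

  strides <- make_constant_strides(50, bout_id = 1L, law_id = 7L)
  status <- character(50)
  ev <- NULL
  for (i in 1:50) {
    res <- ingest_step(buf, strides[[i]], est_speed = 1.3)
    buf <- res$buffer
    status[i] <- res$status
    if (!is.null(res$evaluation)) ev <- res$evaluation
  }
  expect_equal(status[44], "complete")
  expect_true(all(status[c(1:43, 45:50)] == "accumulating"))
  expect_equal(ev$n_strides, 38L)            # first six discarded
  expect_length(ev$features$vector, 64)
  expect_equal(ev$mean_speed, 1.3)
  expect_equal(ev$law_norm, c(0.5, 0.5))

  # a bout boundary before 44 steps restarts with the same law
  buf2 <- evaluation_buffer(law, law_id = 7L)
  for (i in 1:30)
    buf2 <- ingest_step(buf2, make_constant_strides(1, bout_id = 1L, law_id = 7L)[[1]], 1.3)$buffer
  res <- ingest_step(buf2, make_constant_strides(1, bout_id = 2L, law_id = 7L)[[1]], 1.3)
  expect_equal(res$status, "restarted")
  expect_length(res$buffer$strides, 1)

  # two consecutive 22-step bouts never complete
  buf3 <- evaluation_buffer(law, law_id = 7L)
  done <- FALSE
  for (b in 1:2) for (i in 1:22) {
    r <- ingest_step(buf3, make_constant_strides(1, bout_id = b, law_id = 7L)[[1]], 1.3)
    buf3 <- r$buffer
    if (r$status == "complete") done <- TRUE
  }
  expect_false(done)

  expect_error(
    ingest_step(buf, make_constant_strides(1, law_id = 9L)[[1]], 1.3),
    "protocol error")
})

test_that("real-world optimizer fixes timing parameters and uses six laws per bin", {
  rw <- withr::with_seed(5, rw_init())
  for (b in 1:3) {
    bs <- rw$bin_states[[b]]
    expect_equal(bs$state$k, 6L)
    expect_equal(bs$state$d, 2L)
    expect_equal(bs$state$sigma, 0.1)
    expect_equal(nrow(bs$queue), 6)
  }
  cand <- rw_next_candidate(rw, 2)
  expect_equal(cand$law$peak_time, 54.6)
  expect_equal(cand$law$fall_time, 10)
})

test_that("cross-bin updates scale with sigma, clip to the box, and reset paths", {
  rw <- withr::with_seed(6, rw_init(start = c(0.5, 0.5)))
  rw$bin_states[[1]]$state$sigma <- 0       # converged bin
  rw$bin_states[[3]]$state$sigma <- 0.05
  rw$bin_states[[3]]$state$ps <- c(1, 1)
  shift <- c(0.2, 0)
  out <- cross_bin_update(rw, updated_bin = 2, mean_shift = shift)
  expect_equal(out$bin_states[[1]]$state$mean, c(0.5, 0.5))       # sigma 0: no move
  expect_equal(out$bin_states[[3]]$state$mean, c(0.6, 0.5))       # half sigma: half shift
  expect_equal(out$bin_states[[3]]$state$ps, c(0, 0))             # paths reset
  expect_equal(out$bin_states[[2]]$state$mean, c(0.5, 0.5))       # updated bin untouched

  # full-sigma bin receives the full shift; means never leave [0,1]
  rw2 <- withr::with_seed(7, rw_init(start = c(0.95, 0.5)))
  out2 <- cross_bin_update(rw2, 1, c(0.2, -0.1))
  expect_equal(out2$bin_states[[2]]$state$mean, c(1, 0.4))
})

test_that("a complete generation updates its own bin and only shifts the others", {
  rw <- withr::with_seed(8, rw_init(start = c(0.4, 0.6)))
  expect_error(update_bin(rw, 1, rank_by_value(1:6)), "protocol error")

  mkfeat <- function(x) {
    law <- control_law(x[1], 54.6, 20 + 20 * x[2], 10, validate = FALSE)
    bin_condition(make_constant_strides(2), law)
  }
  target <- c(0.8, 0.4)
  ranker <- function(feats) {
    xs <- t(vapply(feats, function(f)
      c(f$torque_params[[1]], (f$torque_params[[3]] - 20) / 20), numeric(2)))
    rank_by_value(rowSums(sweep(xs, 2, target)^2))
  }
  old <- rw
  for (e in 1:6) {
    cand <- rw_next_candidate(rw, 2); rw <- cand$rw
    ev <- list(law = cand$law, law_id = 1L, law_norm = cand$x,
               features = mkfeat(cand$x), mean_speed = 1.3, n_strides = 38L)
    rec <- rw_record_evaluation(rw, ev, ranker)
    rw <- rec$rw
    expect_equal(rec$bin, 2L)
  }
  expect_true(rec$updated)
  new_mean <- rw$bin_states[[2]]$state$mean
  old_mean <- old$bin_states[[2]]$state$mean
  # recombination moves toward the oracle target
  expect_lt(sum((new_mean - target)^2), sum((old_mean - target)^2))
  # other bins: mean shifted by the full cross-bin rule, covariance untouched
  shift <- rw$bin_states[[2]]$state$mean_shift
  expect_equal(rw$bin_states[[1]]$state$mean,
               pmin(pmax(old$bin_states[[1]]$state$mean + shift, 0), 1))
  expect_equal(rw$bin_states[[1]]$state$C, old$bin_states[[1]]$state$C)
  expect_equal(rw$bin_states[[1]]$state$generation, 0L)
})

test_that("with coupling disabled each bin equals an independent optimizer run", {
  target <- c(0.75, 0.35)
  mkfeat <- function(x) {
    law <- control_law(x[1], 54.6, 20 + 20 * x[2], 10, validate = FALSE)
    bin_condition(make_constant_strides(2), law)
  }
  ranker <- function(feats) {
    xs <- t(vapply(feats, function(f)
      c(f$torque_params[[1]], (f$torque_params[[3]] - 20) / 20), numeric(2)))
    rank_by_value(rowSums(sweep(xs, 2, target)^2))
  }
  rw <- withr::with_seed(9, rw_init(start = c(0.5, 0.5), sigma_cap = FALSE))
  ref <- withr::with_seed(9, init_optimizer(c(0.5, 0.5), parameter_bounds(2)))

  for (g in 1:3) {
    X <- matrix(NA_real_, 6, 2)
    for (e in 1:6) {
      cand <- rw_next_candidate(rw, 1); rw <- cand$rw
      X[e, ] <- cand$x
      ev <- list(law = cand$law, law_id = 1L, law_norm = cand$x,
                 features = mkfeat(cand$x), mean_speed = 1.0, n_strides = 38L)
      rw <- rw_record_evaluation(rw, ev, ranker, cross_bin = FALSE)$rw
    }
    ref <- cmaes_tell(ref, rank_by_value(rowSums(sweep(X, 2, target)^2)),
                      points = X)
  }
  bs <- rw$bin_states[[1]]$state
  expect_equal(bs$mean, ref$mean)
  expect_equal(bs$C, ref$C)
  expect_equal(bs$sigma, ref$sigma)
  expect_equal(bs$generation, ref$generation)
})

test_that("a short simulated session honours the buffer contract end to end", {
  part <- sim_participant(15)
  res <- run_session(part, ranker = oracle_ranker(part), seed = 21,
                     duration_s = 900)
  expect_s3_class(res, "session_log")
  expect_true(all(res$log$n_strides == 38))
  expect_true(all(res$log$bin %in% 1:3))
  expect_equal(sum(res$evals_per_bin), nrow(res$log))
  for (b in 1:3) {
    tr <- res$sigma_traces[[b]]
    expect_equal(tr[1], 0.1)
    expect_true(all(diff(tr) <= 1e-12))   # step size never grows
    expect_length(tr, res$rw$bin_states[[b]]$state$generation + 1L)
  }
  # identical seeds reproduce the session exactly
  res2 <- run_session(part, ranker = oracle_ranker(part), seed = 21,
                      duration_s = 900)
  expect_equal(res$log, res2$log)
  expect_equal(res$final_means, res2$final_means)
})
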