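#' Real-world walking-speed bins
#'
#' Three bins split at the 33rd and 66th percentiles of real-world walking
#' speed: below 1.22 m s^-1, between 1.22 and 1.38 m s^-1 (closed on both
#' edges), and above 1.38 m s^-1. Each bin holds an independent optimization
#' state.
#'
#' @param boundaries Strictly increasing bin edges, m s^-1.
#' @return A `speed_bins` object.
#' @export
speed_bins <- function(boundaries = c(1.22, 1.38)) {
  if (any(diff(boundaries) <= 0))
    stop("bin boundaries must be strictly increasing", call. = FALSE)
  structure(list(boundaries = boundaries, n = length(boundaries) + 1L),
            class = "speed_bins")
}

#' Assign an evaluation to a speed bin
#'
#' The bin is chosen by the mean of the per-step estimated speeds collected
#' under the control law; the middle bin is closed on both edges.
#'
#' @param bins A `speed_bins`.
#' @param speeds Per-step speed estimates (or a single mean speed), m s^-1.
#' @return Bin index (1 = slow).
#' @export
assign_bin <- function(bins, speeds) {
  if (!length(speeds)) stop("need at least one speed estimate", call. = FALSE)
  m <- mean(speeds)
  b <- bins$boundaries
  if (m < b[1]) 1L else if (m <= b[2]) 2L else 3L
}

#' Create an empty 44-step evaluation buffer
#'
#' Accumulates consecutive same-bout strides under one control law. If the
#' bout ends before `required_steps` strides are collected, the buffer is
#' cleared and the same control law is retried on the next bout; data never
#' carry over across bouts or laws.
#'
#' @param law The `control_law` under evaluation.
#' @param law_id Identifier of that law.
#' @param law_norm Normalized free parameters of the law (kept with the
#'   completed evaluation for the optimizer update).
#' @param required_steps Steps needed for a complete evaluation (default 44).
#' @return An `evaluation_buffer`.
#' @export
evaluation_buffer <- function(law, law_id = 1L, law_norm = NULL,
                              required_steps = 44) {
  structure(list(law = law, law_id = law_id, law_norm = law_norm,
                 required_steps = as.integer(required_steps),
                 strides = list(), speeds = numeric(), bout_id = NA),
            class = "evaluation_buffer")
}

#' Ingest one stride into an evaluation buffer
#'
#' @param buffer An `evaluation_buffer`.
#' @param stride A `stride_record` tagged with the active law and bout.
#' @param est_speed Estimated walking speed for this step, m s^-1.
#' @return List with `buffer` (updated), `status` (`"accumulating"`,
#'   `"restarted"` or `"complete"`), and on completion `evaluation`: the
#'   binned features (first six strides discarded), mean estimated speed,
#'   law and normalized parameters.
#' @export
ingest_step <- function(buffer, stride, est_speed) {
  if (!identical(stride$law_id, buffer$law_id))
    stop("protocol error: stride law ", stride$law_id,
         " does not match buffer law ", buffer$law_id, call. = FALSE)
  status <- "accumulating"
  if (length(buffer$strides) > 0 && !identical(stride$bout_id, buffer$bout_id)) {
    buffer$strides <- list()      # bout ended early: start over, same law
    buffer$speeds <- numeric()
    status <- "restarted"
  }
  buffer$bout_id <- stride$bout_id
  buffer$strides[[length(buffer$strides) + 1]] <- stride
  buffer$speeds <- c(buffer$speeds, est_speed)
  evaluation <- NULL
  if (length(buffer$strides) == buffer$required_steps) {
    evaluation <- list(
      law = buffer$law, law_id = buffer$law_id, law_norm = buffer$law_norm,
      features = bin_condition(discard_adaptation(buffer$strides), buffer$law),
      mean_speed = mean(buffer$speeds), speeds = buffer$speeds,
      n_strides = length(buffer$strides) - 6L, bout_id = buffer$bout_id)
    buffer$strides <- list()
    buffer$speeds <- numeric()
    status <- "complete"
  }
  list(buffer = buffer, status = status, evaluation = evaluation)
}

rw_candidate_law <- function(x, fixed_peak_time, fixed_fall_time) {
  apply_timing_constraint(
    denormalize_law(x, parameter_bounds(2), peak_time = fixed_peak_time,
                    fall_time = fixed_fall_time),
    toe_off = 62, fall_min = fixed_fall_time)
}

#' Initialize the opportunistic real-world optimizer
#'
#' One independent two-parameter (peak torque, rise time) CMA-ES per speed
#' bin, six control laws per generation, with peak time and fall time fixed
#' (defaults 54.6% and 10.0% of the gait cycle). Each bin starts with a
#' sampled queue of candidate laws.
#'
#' @param start Starting normalized (peak_torque, rise_time) vector or a
#'   `control_law`.
#' @param bins A `speed_bins`.
#' @param sigma Initial step size (default 0.1).
#' @param fixed_peak_time,fixed_fall_time Fixed timing parameters, percent
#'   gait cycle.
#' @param sigma_cap Keep each bin's step size non-increasing (default TRUE).
#'   In the opportunistic setting sigma doubles as the remaining-uncertainty
#'   measure that scales cross-bin coupling, so it only shrinks as evidence
#'   accumulates; the laboratory optimizer uses unmodified step-size
#'   adaptation.
#' @return An `rw_optimizer`.
#' @export
rw_init <- function(start = generic_law(), bins = speed_bins(), sigma = 0.1,
                    fixed_peak_time = 54.6, fixed_fall_time = 10,
                    sigma_cap = TRUE) {
  b2 <- parameter_bounds(2)
  x0 <- if (inherits(start, "control_law")) normalize_law(start, b2) else start
  mk <- function() {
    st <- init_optimizer(unname(x0), b2, sigma = sigma)
    plan <- cmaes_ask(st, peak_time = fixed_peak_time,
                      fall_time = fixed_fall_time)
    list(state = plan$state, queue = plan$samples, qpos = 1L, evals = list(),
         sigma_trace = sigma)
  }
  structure(list(bins = bins, sigma0 = sigma,
                 fixed_peak_time = fixed_peak_time,
                 fixed_fall_time = fixed_fall_time, sigma_cap = sigma_cap,
                 bin_states = list(mk(), mk(), mk())),
            class = "rw_optimizer")
}

#' @export
print.rw_optimizer <- function(x, ...) {
  for (b in seq_along(x$bin_states)) {
    bs <- x$bin_states[[b]]
    cat(sprintf("bin %d: gen %d, sigma %.4f, mean (%.3f, %.3f), %d pending evals\n",
                b, bs$state$generation, bs$state$sigma, bs$state$mean[1],
                bs$state$mean[2], length(bs$evals)))
  }
  invisible(x)
}

#' Draw the next candidate control law for a bin
#'
#' Takes the next unevaluated candidate from the bin's sampled queue,
#' resampling a fresh set from the bin's current distribution if the queue is
#' exhausted before a full generation completes in that bin.
#'
#' @param rw An `rw_optimizer`.
#' @param bin Bin index.
#' @return List with updated `rw`, the candidate `law`, its normalized
#'   parameters `x`, and the source `bin`.
#' @export
rw_next_candidate <- function(rw, bin) {
  bs <- rw$bin_states[[bin]]
  if (bs$qpos > nrow(bs$queue)) {
    plan <- cmaes_ask(bs$state, peak_time = rw$fixed_peak_time,
                      fall_time = rw$fixed_fall_time)
    bs$state <- plan$state
    bs$queue <- plan$samples
    bs$qpos <- 1L
  }
  x <- bs$queue[bs$qpos, ]
  bs$qpos <- bs$qpos + 1L
  rw$bin_states[[bin]] <- bs
  list(rw = rw, law = rw_candidate_law(x, rw$fixed_peak_time, rw$fixed_fall_time),
       x = x, bin = bin)
}

#' Apply the sigma-proportional cross-bin mean update
#'
#' When one bin's optimizer updates its mean by `mean_shift`, every other
#' bin's mean is shifted by `(sigma_b / sigma_init) * mean_shift`, clipped to
#' the unit box. Bins that have converged (small sigma) are barely moved;
#' early on (sigma near its initial value) the full shift propagates.
#' Because the shift changes a bin's mean outside its own update equations,
#' the receiving bin's evolution paths no longer describe its sampling
#' history and are reset (the standard treatment of externally injected mean
#' changes).
#'
#' @param rw An `rw_optimizer`.
#' @param updated_bin Index of the bin that performed the update.
#' @param mean_shift Normalized mean shift of that bin.
#' @return The updated `rw_optimizer`.
#' @export
cross_bin_update <- function(rw, updated_bin, mean_shift) {
  for (b in seq_along(rw$bin_states)) {
    if (b == updated_bin) next
    bs <- rw$bin_states[[b]]
    adj <- (bs$state$sigma / rw$sigma0) * mean_shift
    if (any(adj != 0)) {
      bs$state$mean <- pmin(pmax(bs$state$mean + adj, 0), 1)
      bs$state$ps <- numeric(bs$state$d)
      bs$state$pc <- numeric(bs$state$d)
    }
    rw$bin_states[[b]] <- bs
  }
  rw
}

#' Record a completed 44-step evaluation
#'
#' The evaluation is credited to the speed bin of its mean estimated speed.
#' When that bin holds a complete generation (six evaluations), the bin is
#' updated via [update_bin()].
#'
#' @param rw An `rw_optimizer`.
#' @param evaluation A completed evaluation from [ingest_step()].
#' @param ranker Function mapping a list of condition features to a
#'   `ranking_result` (e.g. built from a trained classifier).
#' @param cross_bin Propagate the mean update to the other bins?
#' @return List with updated `rw`, the credited `bin`, and `updated` (TRUE if
#'   a generation completed and the bin was updated).
#' @export
rw_record_evaluation <- function(rw, evaluation, ranker, cross_bin = TRUE) {
  bin <- assign_bin(rw$bins, evaluation$mean_speed)
  bs <- rw$bin_states[[bin]]
  bs$evals[[length(bs$evals) + 1]] <- evaluation
  rw$bin_states[[bin]] <- bs
  updated <- FALSE
  if (length(bs$evals) == bs$state$k) {
    ranking <- ranker(lapply(bs$evals, `[[`, "features"))
    rw <- update_bin(rw, bin, ranking, cross_bin = cross_bin)
    updated <- TRUE
  }
  list(rw = rw, bin = bin, updated = updated)
}

#' Update one speed bin's optimizer from a completed generation
#'
#' Performs the CMA-ES tell on the bin's six evaluated control laws (using
#' the evaluated normalized parameters), applies the sigma-proportional
#' cross-bin update to the other bins, clears the bin's evaluations and
#' samples a fresh candidate queue for it.
#'
#' @param rw An `rw_optimizer`.
#' @param bin Bin index with a complete pending generation.
#' @param ranking A `ranking_result` over that bin's evaluations.
#' @param cross_bin Propagate the mean update to the other bins?
#' @return The updated `rw_optimizer`.
#' @export
update_bin <- function(rw, bin, ranking, cross_bin = TRUE) {
  bs <- rw$bin_states[[bin]]
  if (length(bs$evals) != bs$state$k)
    stop("protocol error: bin ", bin, " has ", length(bs$evals),
         " evaluations, needs ", bs$state$k, call. = FALSE)
  X <- do.call(rbind, lapply(bs$evals, `[[`, "law_norm"))
  sigma_old <- bs$state$sigma
  bs$state <- cmaes_tell(bs$state, ranking, points = X)
  if (isTRUE(rw$sigma_cap))
    bs$state$sigma <- min(bs$state$sigma, sigma_old)
  shift <- bs$state$mean_shift
  bs$evals <- list()
  plan <- cmaes_ask(bs$state, peak_time = rw$fixed_peak_time,
                    fall_time = rw$fixed_fall_time)
  bs$state <- plan$state
  bs$queue <- plan$samples
  bs$qpos <- 1L
  bs$sigma_trace <- c(bs$sigma_trace, bs$state$sigma)
  rw$bin_states[[bin]] <- bs
  if (cross_bin) rw <- cross_bin_update(rw, bin, shift)
  rw
}

#' Run an opportunistic real-world optimization session
#'
#' Simulates a naturalistic session: the participant walks the scheduled
#' bouts while the optimizer accumulates 44-continuous-step evaluations of
#' candidate control laws, bins them by mean estimated speed, and updates the
#' per-bin two-parameter optimizers. The active candidate is drawn from the
#' bin matching the most recent speed estimate; an evaluation interrupted by
#' a bout end restarts with the same law on the next bout.
#'
#' @param participant A `sim_participant`.
#' @param classifier An `exo_classifier` used to rank generations (ignored if
#'   `ranker` is given).
#' @param ranker Optional ranking function (features list -> `ranking_result`),
#'   e.g. a ground-truth oracle in tests.
#' @param schedule A `session_schedule`; default one naturalistic hour.
#' @param seed Session seed.
#' @param duration_s Session length if `schedule` is NULL.
#' @param start Starting law or normalized (peak_torque, rise_time) vector.
#' @param cross_bin Apply cross-bin updates? (TRUE; FALSE isolates the bins.)
#' @return A `session_log`: per-evaluation data frame, per-bin sigma traces,
#'   final laws and normalized means per bin, ground-truth bin optima,
#'   normalized distances of final and starting means to the optima, and
#'   evaluation counts.
#' @export
run_session <- function(participant, classifier = NULL, ranker = NULL,
                        schedule = NULL, seed = 1, duration_s = 3600,
                        start = generic_law(), cross_bin = TRUE) {
  if (is.null(ranker)) {
    if (is.null(classifier))
      stop("need a classifier or a ranker", call. = FALSE)
    ranker <- function(feats) rank_laws(classifier, feats)
  }
  withr::with_seed(seed, {
    if (is.null(schedule))
      schedule <- generate_schedule("naturalistic", duration_s = duration_s)
    model <- calibrate_speed_model(participant)
    rw <- rw_init(start)
    last_speed <- 1.25
    cand <- rw_next_candidate(rw, assign_bin(rw$bins, last_speed))
    rw <- cand$rw
    law_counter <- 1L
    buffer <- evaluation_buffer(cand$law, law_counter, cand$x)
    log_rows <- list()
    for (b in seq_len(nrow(schedule))) {
      sp <- schedule$target_speed[b]
      remaining <- schedule$n_steps[b]
      first_chunk <- TRUE
      while (remaining > 0) {
        chunk <- min(remaining, buffer$required_steps - length(buffer$strides))
        strides <- generate_strides(participant, buffer$law, sp, chunk,
                                    transient = length(buffer$strides) == 0,
                                    bout_id = b, law_id = buffer$law_id,
                                    context = "outdoor")
        periods <- vapply(strides, `[[`, numeric(1), "stride_period")
        est <- as.numeric(estimate_speed(model, periods))
        for (i in seq_len(chunk)) {
          res <- ingest_step(buffer, strides[[i]], est[i])
          buffer <- res$buffer
          if (res$status == "complete") {
            rec <- rw_record_evaluation(rw, res$evaluation, ranker,
                                        cross_bin = cross_bin)
            rw <- rec$rw
            log_rows[[length(log_rows) + 1]] <- data.frame(
              bout = b, bin = rec$bin, mean_speed = res$evaluation$mean_speed,
              n_strides = res$evaluation$n_strides, updated = rec$updated,
              peak_torque = res$evaluation$law$peak_torque,
              rise_time = res$evaluation$law$rise_time)
            last_speed <- res$evaluation$mean_speed
            cand <- rw_next_candidate(rw, assign_bin(rw$bins, last_speed))
            rw <- cand$rw
            law_counter <- law_counter + 1L
            buffer <- evaluation_buffer(cand$law, law_counter, cand$x)
          }
        }
        remaining <- remaining - chunk
        first_chunk <- FALSE
      }
    }
    bin_speeds <- c(1.05, 1.30, 1.50)
    optima <- t(vapply(bin_speeds,
                       function(s) true_optimum(participant, s, "outdoor")[c(1, 3)],
                       numeric(2)))
    finals <- t(vapply(rw$bin_states, function(bs) bs$state$mean, numeric(2)))
    b2 <- parameter_bounds(2)
    x0 <- if (inherits(start, "control_law")) normalize_law(start, b2) else start
    structure(list(
      rw = rw,
      log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
      sigma_traces = lapply(rw$bin_states, `[[`, "sigma_trace"),
      final_means = finals,
      final_laws = lapply(seq_len(3), function(b)
        rw_candidate_law(finals[b, ], rw$fixed_peak_time, rw$fixed_fall_time)),
      bin_optima = optima,
      final_dist = rowSums(abs(finals - optima)) / 2,
      start_dist = rowSums(abs(matrix(unname(x0), 3, 2, byrow = TRUE) - optima)) / 2,
      evals_per_bin = vapply(seq_len(3), function(b)
        if (is.null(log_rows)) 0L else
          sum(vapply(log_rows, function(r) r$bin == b, logical(1))), integer(1)),
      seed = seed), class = "session_log")
  })
}

#' @export
print.session_log <- function(x, ...) {
  cat("Real-world optimization session (seed", x$seed, ")\n")
  cat("evaluations per bin:", paste(x$evals_per_bin, collapse = " "), "\n")
  cat("mean normalized distance to bin optima:",
      sprintf("%.3f (start %.3f)", mean(x$final_dist), mean(x$start_dist)), "\n")
  invisible(x)
}
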