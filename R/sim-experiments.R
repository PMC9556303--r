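#' Simulate the prior training dataset and train the classifier
#'
#' Emulates the previously collected laboratory dataset that the preference
#' classifier is trained on: a pool of training participants each walks under
#' many uniformly sampled control laws; each condition yields binned
#' kinematic features (30-s evaluations, first six strides discarded) and a
#' noisy 2-min steady-state metabolic cost. Pairwise differences are labelled
#' within participant and pooled.
#'
#' @param n_participants Training participants.
#' @param n_conditions Control laws per participant.
#' @param seed Seed (participants derive their own seeds from it).
#' @param speed Treadmill speed, m s^-1.
#' @param eval_seconds Kinematic evaluation time per law, s.
#' @return A `training_pairs` object pooled across participants.
#' @export
simulate_prior_dataset <- function(n_participants = 5, n_conditions = 160,
                                   seed = 1, speed = 1.25, eval_seconds = 30) {
  withr::with_seed(seed, {
    parts <- lapply(seq_len(n_participants),
                    function(i) sim_participant(seed * 1000 + i))
    all_X <- list(); all_y <- list(); all_m <- list()
    b4 <- parameter_bounds(4)
    for (p in parts) {
      feats <- vector("list", n_conditions)
      costs <- numeric(n_conditions)
      for (i in seq_len(n_conditions)) {
        law <- apply_timing_constraint(denormalize_law(runif(4), b4))
        period <- p$period_intercept + p$period_slope * speed
        n_str <- max(10, round(eval_seconds / period))
        strides <- generate_strides(p, law, speed, n_str)
        feats[[i]] <- bin_condition(discard_adaptation(strides), law)
        costs[i] <- metabolic_rate(p, law, speed, noisy = TRUE)
      }
      tp <- build_training_pairs(feats, costs)
      all_X[[length(all_X) + 1]] <- tp$X
      all_y[[length(all_y) + 1]] <- tp$y
      all_m[[length(all_m) + 1]] <- tp$margin
    }
    structure(list(X = do.call(rbind, all_X), y = unlist(all_y),
                   margin = unlist(all_m), pairs = NULL),
              class = "training_pairs")
  })
}

#' Fit a stride-period speed model from a simulated calibration walk
#'
#' @param participant A `sim_participant`.
#' @param speeds Calibration speeds, m s^-1.
#' @param strides_per_speed Strides per calibration speed.
#' @param seed Optional seed.
#' @return A `speed_model`.
#' @export
calibrate_speed_model <- function(participant, speeds = seq(0.8, 1.7, by = 0.1),
                                  strides_per_speed = 10, seed = NULL) {
  gen <- function() {
    periods <- unlist(lapply(speeds, function(s)
      pmax(participant$period_intercept + participant$period_slope * s +
             rnorm(strides_per_speed, 0, participant$period_sd), 0.5)))
    fit_speed_model(periods, rep(speeds, each = strides_per_speed))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Run one laboratory optimization protocol on a simulated participant
#'
#' Executes the generation loop against the simulated participant. The
#' `"metabolic"` method ranks each generation by noisy simulated 2-min
#' steady-state metabolic rate (the laboratory oracle); the `"datadriven"`
#' method simulates 30 s of strides per law, bins them, and ranks with the
#' trained preference classifier.
#'
#' @param participant A `sim_participant`.
#' @param method `"datadriven"` or `"metabolic"`.
#' @param classifier An `exo_classifier` (required for `"datadriven"`).
#' @param generations Number of generations (default 8).
#' @param seed Seed for the whole protocol.
#' @param speed Treadmill speed, m s^-1.
#' @param start Starting `control_law`.
#' @param eval_seconds Seconds of walking per law.
#' @return List: final `state`, `final_mean`, `optimum` (normalized ground
#'   truth), `dist_to_optimum` and `start_dist` (normalized Euclidean),
#'   `sigma_trace`, `minutes` of simulated walking.
#' @export
run_lab_optimization <- function(participant, method = c("datadriven", "metabolic"),
                                 classifier = NULL, generations = 8, seed = 1,
                                 speed = 1.25, start = generic_law(),
                                 eval_seconds = if (method[1] == "metabolic") 120 else 30) {
  method <- match.arg(method)
  if (method == "datadriven" && is.null(classifier))
    stop("datadriven method needs a trained classifier", call. = FALSE)
  withr::with_seed(seed, {
    b4 <- parameter_bounds(4)
    state <- init_optimizer(start, b4)
    opt <- true_optimum(participant, speed)
    sigma_trace <- state$sigma
    for (g in seq_len(generations)) {
      plan <- cmaes_ask(state, toe_off = 100 * stance_fraction(speed))
      state <- plan$state
      if (method == "metabolic") {
        vals <- vapply(plan$laws, function(l)
          metabolic_rate(participant, l, speed, noisy = TRUE), numeric(1))
        ranking <- rank_by_value(vals)
      } else {
        period <- participant$period_intercept + participant$period_slope * speed
        n_str <- max(10, round(eval_seconds / period))
        feats <- lapply(plan$laws, function(l)
          bin_condition(discard_adaptation(
            generate_strides(participant, l, speed, n_str)), l))
        ranking <- rank_laws(classifier, feats)
      }
      state <- cmaes_tell(state, ranking)
      sigma_trace <- c(sigma_trace, state$sigma)
    }
    list(state = state, final_mean = state$mean, optimum = opt,
         dist_to_optimum = sqrt(sum((state$mean - opt)^2)),
         start_dist = sqrt(sum((normalize_law(start, b4) - opt)^2)),
         sigma_trace = sigma_trace,
         minutes = protocol_duration(generations, state$k, eval_seconds))
  })
}

#' Normalized parameter distance between two optimization outcomes
#'
#' Mean absolute difference across parameters, as a percentage of each
#' parameter's allowable range.
#'
#' @param a,b Normalized parameter vectors.
#' @return Distance in percent of the normalized range.
#' @export
param_distance_pct <- function(a, b) 100 * mean(abs(a - b))

#' Run a full virtual experiment
#'
#' Binds the simulator and the optimization machinery into the study
#' protocols: `lab_metabolic_opt` (8 generations x 8 laws x 2 min),
#' `lab_datadriven_opt` (30 s per law), `realworld_opt` (one hour of
#' naturalistic bouts, see [run_session()]), or `validation` (6-min treadmill
#' conditions evaluated through the respirometry pipeline).
#'
#' @param participant A `sim_participant`.
#' @param protocol Protocol name.
#' @param seed Seed.
#' @param classifier Trained `exo_classifier` (data-driven and real-world
#'   protocols).
#' @param ... Passed to the underlying runner.
#' @return Protocol-specific result list.
#' @export
run_virtual_experiment <- function(participant,
                                   protocol = c("lab_datadriven_opt",
                                                "lab_metabolic_opt",
                                                "realworld_opt", "validation"),
                                   seed = 1, classifier = NULL, ...) {
  protocol <- match.arg(protocol)
  switch(protocol,
    lab_datadriven_opt = run_lab_optimization(participant, "datadriven",
                                              classifier, seed = seed, ...),
    lab_metabolic_opt = run_lab_optimization(participant, "metabolic",
                                             seed = seed, ...),
    realworld_opt = run_session(participant, classifier = classifier,
                                seed = seed, ...),
    validation = run_validation(participant, seed = seed, ...))
}

#' Simulated treadmill validation of assistance conditions
#'
#' Each condition is a 6-min treadmill walk preceded by quiet standing and
#' followed by 3 min of standing recovery; breath-by-breath respirometry is
#' simulated from the participant's true power trace and the energetic
#' outcomes recomputed through the metabolics pipeline.
#'
#' @param participant A `sim_participant`.
#' @param laws Named list of `control_law`s (the conditions).
#' @param speed Treadmill speed, m s^-1.
#' @param seed Seed.
#' @return Data frame with one row per condition: steady-state net rate,
#'   cumulative cost, cost of transport, and percent change versus the first
#'   condition.
#' @export
run_validation <- function(participant, laws = list(zero_torque = zero_torque_law(),
                                                    generic = generic_law()),
                           speed = 1.25, seed = 1) {
  withr::with_seed(seed, {
    mass <- participant$body_mass
    dt <- 1
    stand_w <- 240; walk_w <- 360; recov_w <- 240
    rows <- lapply(names(laws), function(nm) {
      rate <- metabolic_rate(participant, laws[[nm]], speed)      # net W/kg
      p_true <- c(rep(participant$standing_rate, stand_w),
                  rep(participant$standing_rate + rate, walk_w),
                  rep(participant$standing_rate, recov_w)) * mass
      breaths <- generate_breaths(participant, p_true, dt)
      base <- standing_baseline(breaths, mass, window = c(0, stand_w))
      en <- condition_energetics(breaths, mass, base, stand_w, stand_w + walk_w,
                                 distance = speed * walk_w, recovery = 180)
      cbind(condition = nm, true_rate = rate, en)
    })
    out <- do.call(rbind, rows)
    out$pct_change_steady <- percent_change(out$steady_rate, out$steady_rate[1])
    out
  })
}
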