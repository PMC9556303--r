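test_that("the metabolic landscape is quadratic with its minimum at the stored optimum", {
  part <- sim_participant(6)
  opt_law <- denormalize_law(part$optima[2, ], parameter_bounds(4))
  expect_equal(metabolic_rate(part, opt_law, 1.25), part$base_rates[2],
               tolerance = 1e-10)

  # symmetric displacements along a curvature eigenvector give equal rates
  xs <- part$optima[2, ]
  for (i in 1:4) {
    d <- min(xs[i], 1 - xs[i], 0.04)
    up <- xs; up[i] <- xs[i] + d
    dn <- xs; dn[i] <- xs[i] - d
    expect_equal(metabolic_rate(part, denormalize_law(up, parameter_bounds(4)), 1.25),
                 metabolic_rate(part, denormalize_law(dn, parameter_bounds(4)), 1.25),
                 tolerance = 1e-10)
  }

  # any displacement costs energy
  set.seed(3)
  for (r in 1:20) {
    x <- runif(4)
    expect_gte(metabolic_rate(part, denormalize_law(x, parameter_bounds(4)), 1.25),
               part$base_rates[2])
  }

  # outdoor optima are shifted toward larger peak torque
  expect_gt(true_optimum(part, 1.25, "outdoor")[1], true_optimum(part, 1.25)[1])
})

test_that("noisy metabolic samples scatter around the true landscape value", {
  part <- sim_participant(6)
  law <- generic_law()
  truth <- metabolic_rate(part, law, 1.25)
  set.seed(12)
  draws <- replicate(400, metabolic_rate(part, law, 1.25, noisy = TRUE))
  expect_lt(abs(mean(draws) - truth), 3 * part$metabolic_noise_sd / sqrt(400))
  expect_lt(abs(sd(draws) - part$metabolic_noise_sd), 0.02)
})

test_that("stride generation is seeded, law-responsive and speed-dependent", {
  part <- sim_participant(7)
  a <- generate_strides(part, generic_law(), 1.25, 10, seed = 3)
  b <- generate_strides(part, generic_law(), 1.25, 10, seed = 3)
  expect_identical(a, b)

  # larger peak torque (same timing) -> more late-stance plantarflexion
  lo <- apply_timing_constraint(control_law(0.1, 50, 30, 10))
  hi <- apply_timing_constraint(control_law(0.9, 50, 30, 10))
  f_lo <- bin_condition(discard_adaptation(
    generate_strides(part, lo, 1.25, 306, seed = 4)), lo)
  f_hi <- bin_condition(discard_adaptation(
    generate_strides(part, hi, 1.25, 306, seed = 5)), hi)
  expect_lt(mean(f_hi$angle_bins[17:19]), mean(f_lo$angle_bins[17:19]))
  # early stance precedes both torque onset and push-off: unaffected
  expect_lt(max(abs(f_hi$angle_bins[1:5] - f_lo$angle_bins[1:5])), 0.3)

  # stride periods track the speed map
  per <- vapply(generate_strides(part, generic_law(), 1.75, 300, seed = 6),
                `[[`, numeric(1), "stride_period")
  expect_lt(abs(mean(per) - (1.475 - 0.3 * 1.75)), 0.01)

  # adaptation transient: early strides deviate more from the post-adaptation mean
  strides <- generate_strides(part, generic_law(), 1.25, 200, seed = 8)
  late <- bin_condition(strides[7:200], generic_law())$angle_bins
  first <- bin_condition(strides[1], generic_law())$angle_bins
  expect_gt(max(abs(first - late)), 2)
})

test_that("simulated respirometry has first-order dynamics that conserve energy", {
  part <- sim_participant(2)
  tau <- part$sensor_tau

  # step response reaches 63.2% of the step at t = tau
  step <- c(100, rep(200, 400))
  b <- generate_breaths(part, step, 1, seed = 3, noise_cv = 0)
  p <- breath_power(b$vo2_ml_min, b$vco2_ml_min)
  i <- which.min(abs(b$time_s - tau))
  expect_lt(abs((p[i] - 100) / 100 - (1 - exp(-b$time_s[i] / tau))), 0.02)

  # plateau after ~5 tau
  expect_lt(abs(tail(p, 1) - 200) / 200, 0.01)

  # energy conservation on a finite burst with full recovery
  burst <- c(rep(0, 5), rep(150, 200), rep(0, 6 * tau))
  bb <- generate_breaths(part, burst, 1, seed = 4, noise_cv = 0)
  pb <- breath_power(bb$vo2_ml_min, bb$vco2_ml_min)
  expect_lt(abs(pracma::trapz(bb$time_s, pb) - 150 * 200) / (150 * 200), 0.02)
})

test_that("session schedules match the prescribed treadmill and naturalistic styles", {
  sin_sch <- generate_schedule("treadmill_sinusoid", seed = 1)
  expect_equal(attr(sin_sch, "speed_min"), 0.75)
  expect_equal(attr(sin_sch, "speed_max"), 1.75)
  expect_equal(attr(sin_sch, "period_s"), 30)

  nat <- generate_schedule("naturalistic", duration_s = 150000, seed = 2)
  expect_identical(nat, generate_schedule("naturalistic", duration_s = 150000, seed = 2))
  expect_gt(nrow(nat), 2000)
  bins <- speed_bins()
  share <- table(vapply(nat$target_speed, function(s) assign_bin(bins, s), integer(1)))
  expect_true(all(abs(share / nrow(nat) - 1 / 3) < 0.03))
  expect_true(all(nat$rest_s >= 5 & nat$rest_s <= 10))
  expect_lt(abs(median(nat$n_steps) - 40) / 40, 0.2)
  expect_gt(mean(nat$n_steps < 100), 0.85)   # most bouts are short
})

test_that("the trained classifier separates pairs whose true gap clears the noise", {
  cl <- small_classifier()
  part <- sim_participant(44)
  b4 <- parameter_bounds(4)
  set.seed(19)
  correct <- c()
  while (length(correct) < 40) {
    la <- apply_timing_constraint(denormalize_law(runif(4), b4))
    lb <- apply_timing_constraint(denormalize_law(runif(4), b4))
    gap <- metabolic_rate(part, la, 1.25) - metabolic_rate(part, lb, 1.25)
    if (abs(gap) < 2 * part$metabolic_noise_sd) next
    fa <- bin_condition(discard_adaptation(generate_strides(part, la, 1.25, 27)), la)
    fb <- bin_condition(discard_adaptation(generate_strides(part, lb, 1.25, 27)), lb)
    p <- pair_probability(cl, feature_delta(fa, fb))$p_ij
    correct <- c(correct, (p > 0.5) == (gap < 0))
  }
  expect_gte(mean(correct), 0.75)
})

test_that("virtual lab protocols report the published walking times", {
  part <- sim_participant(3)
  mm <- run_virtual_experiment(part, "lab_metabolic_opt", seed = 2, generations = 1)
  expect_equal(mm$minutes * 8, 128)   # 8 generations x 8 laws x 2 min
  dd <- run_virtual_experiment(part, "lab_datadriven_opt", seed = 2,
                               classifier = small_classifier(), generations = 1)
  expect_equal(dd$minutes * 8, 32)
})

test_that("validation conditions run through the respirometry pipeline coherently", {
  part <- sim_participant(9)
  res <- run_validation(part, laws = list(zero = zero_torque_law(),
                                          generic = generic_law()),
                        seed = 5)
  expect_equal(nrow(res), 2)
  expect_equal(res$cost_of_transport, res$cumulative_energy / res$distance)
  # measured steady rates track the landscape truth through the gas pipeline
  expect_lt(max(abs(res$steady_rate - res$true_rate)), 0.15)
  # generic assistance beats zero torque for a participant centred on generic
  expect_lt(res$steady_rate[2], res$steady_rate[1])
})
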