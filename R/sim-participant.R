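#' Construct a simulated participant
#'
#' A synthetic walker with a ground-truth quadratic metabolic landscape over
#' the normalized torque parameters, per-speed optimal parameters, a
#' torque- and cost-dependent kinematic response, a stride-period map, and a
#' respirometry noise model. The simulated participant is the oracle for
#' desk-scale optimization experiments: the optimizers see only its noisy
#' outputs while tests score against its stored ground truth.
#'
#' The landscape is `rate(law, speed) = base_rate(speed) +
#' 0.5 (x - x*(speed))' K (x - x*(speed))` in normalized parameters, with
#' curvature chosen so the generic-to-optimum offset costs about 0.2 W kg^-1 (the
#' scale of generic-versus-optimized differences), and measurement noise on
#' 2-min steady-state estimates set so generation-scale pairwise sign flips
#' occur at a realistic 10-20% rate. Per-participant optima are
#' drawn around the generic parameters.
#'
#' @param seed Integer seed; fully determines the participant.
#' @param body_mass Body mass, kg.
#' @param metabolic_noise_sd SD of a 2-min noisy steady-state estimate,
#'   W kg^-1.
#' @param optimum_spread SD of the per-participant optimum around the generic
#'   parameters, normalized units.
#' @param kinematic_gain Late-stance plantarflexion shift per unit peak
#'   torque, deg per Nm kg^-1.
#' @param response_gain Plantarflexion shift per unit metabolic benefit, deg
#'   per W kg^-1 (better assistance yields more ankle extension at toe-off).
#' @param amp_noise_sd Per-stride SD of the late-stance amplitude, deg.
#' @param sensor_tau Respirometry first-order time constant, s.
#' @return A `sim_participant`.
#' @export
sim_participant <- function(seed = 1, body_mass = 67,
                            metabolic_noise_sd = 0.10, optimum_spread = 0.10,
                            kinematic_gain = 6, response_gain = 12,
                            amp_noise_sd = 1.5, sensor_tau = 42) {
  withr::with_seed(seed, {
    anchor_speeds <- c(0.75, 1.25, 1.75)
    # centred on the generic assistance parameters, fall time near its
    # lower bound as peak times sit high in the allowable range
    center <- c(0.5, 0.8, 0.5, 0.0)   # normalized (peak_torque, peak_time, rise, fall)
    mid <- pmin(pmax(center + rnorm(4, 0, optimum_spread), c(0.05, 0.05, 0.05, 0)), 0.95)
    shift_slow <- c(-0.15, -0.05, 0.05, 0) + rnorm(4, 0, 0.05)
    shift_fast <- c(0.15, 0.05, -0.05, 0) + rnorm(4, 0, 0.05)
    lo <- c(0.05, 0.05, 0.05, 0)
    optima <- rbind(pmin(pmax(mid + shift_slow, lo), 0.95),
                    mid,
                    pmin(pmax(mid + shift_fast, lo), 0.95))
    # walking outdoors supports larger, slightly later assistance than the
    # treadmill optimum (greater perceived stability outdoors)
    outdoor_shift <- c(0.25, 0, 0.05, 0) + rnorm(4, 0, 0.05)
    structure(list(
      seed = seed, body_mass = body_mass,
      anchor_speeds = anchor_speeds,
      optima = optima,                      # rows: slow/normal/fast, normalized
      outdoor_shift = outdoor_shift,        # added to optima in outdoor context
      K = diag(c(10, 16, 8, 4)),            # W kg^-1 per normalized unit^2; peak-time timing steepest
      base_rates = c(2.2, 3.0, 4.4),        # net W kg^-1 at the optimum per speed
      standing_rate = 1.25,                 # gross standing rate, W kg^-1
      metabolic_noise_sd = metabolic_noise_sd,
      kinematic_gain = kinematic_gain, response_gain = response_gain,
      amp_noise_sd = amp_noise_sd, sample_noise_sd = 0.5,
      period_intercept = 1.475, period_slope = -0.3, period_sd = 0.03,
      rer = 0.85, sensor_tau = sensor_tau),
      class = "sim_participant")
  })
}

#' @export
print.sim_participant <- function(x, ...) {
  cat(sprintf("Simulated participant (seed %d): %.1f kg, noise %.2f W/kg\n",
              x$seed, x$body_mass, x$metabolic_noise_sd))
  cat("Normalized optima (rows = ", paste(x$anchor_speeds, collapse = "/"),
      " m/s):\n", sep = "")
  print(round(x$optima, 3))
  invisible(x)
}

interp_rows <- function(speeds, M, speed) {
  apply(M, 2, function(col) approx(speeds, col, xout = speed, rule = 2)$y)
}

#' Ground-truth optimal parameters at a walking speed
#'
#' @param participant A `sim_participant`.
#' @param speed Walking speed, m s^-1.
#' @param context `"treadmill"` or `"outdoor"`; outdoor optima are shifted
#'   toward larger peak torque (participants tolerate more assistance when
#'   walking overground).
#' @return Normalized 4-vector (interpolated between anchor-speed optima).
#' @export
true_optimum <- function(participant, speed, context = c("treadmill", "outdoor")) {
  context <- match.arg(context)
  x <- interp_rows(participant$anchor_speeds, participant$optima, speed)
  if (context == "outdoor")
    x <- pmin(pmax(x + participant$outdoor_shift, 0), 1)
  x
}

#' Ground-truth metabolic rate of a control law
#'
#' Evaluates the participant's quadratic landscape; the noisy variant adds
#' Gaussian measurement noise emulating a 2-min steady-state respirometry
#' estimate.
#'
#' @param participant A `sim_participant`.
#' @param law A `control_law`.
#' @param speed Walking speed, m s^-1.
#' @param noisy Add measurement noise?
#' @param context `"treadmill"` or `"outdoor"` (see [true_optimum()]).
#' @return Net metabolic rate, W kg^-1.
#' @export
metabolic_rate <- function(participant, law, speed, noisy = FALSE,
                           context = c("treadmill", "outdoor")) {
  x <- normalize_law(law, parameter_bounds(4))
  xs <- true_optimum(participant, speed, context)
  base <- approx(participant$anchor_speeds, participant$base_rates,
                 xout = speed, rule = 2)$y
  r <- base + 0.5 * as.numeric(t(x - xs) %*% participant$K %*% (x - xs))
  if (noisy) r <- r + rnorm(1, 0, participant$metabolic_noise_sd)
  r
}

# baseline ankle-angle template: periodic spline through gait-like knots
# (deg, dorsiflexion positive); returns function of phase in [0, 100)
ankle_template <- function() {
  p <- c(0, 10, 30, 48, 62, 75, 90, 100)
  th <- c(0, -4, 5, 10, -15, -5, 2, 0)
  stats::splinefun(p, th, method = "periodic")
}

late_stance_bump <- function(phase, center, width = 18) {
  u <- (phase - center) / width
  ifelse(abs(u) < 0.5, cos(pi * u)^2, 0)
}

#' Generate strides of a simulated participant
#'
#' Baseline gait-like ankle angle and velocity curves are modulated by the
#' active control law through two channels with distinct timing: a direct
#' mechanical plantarflexion shift shaped like the torque profile itself
#' (so it tracks peak time and rise/fall times), and a human-response shift
#' peaking at toe-off whose amplitude grows with the law's metabolic benefit
#' (better assistance yields more ankle extension at push-off). Per-stride
#' amplitude noise on the response channel and white sample noise are added.
#' The first strides after a law switch carry a decaying adaptation
#' transient. Stride periods are drawn from the participant's speed-dependent
#' stride-period map.
#'
#' @param participant A `sim_participant`.
#' @param law The active `control_law`.
#' @param speed Walking speed, m s^-1.
#' @param n_strides Number of strides.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @param n_samples Samples per stride trajectory.
#' @param transient Include the adaptation transient on the first 6 strides?
#' @param bout_id,law_id Identifiers attached to each stride.
#' @param context `"treadmill"` or `"outdoor"` (see [true_optimum()]).
#' @return List of `stride_record`s.
#' @export
generate_strides <- function(participant, law, speed, n_strides, seed = NULL,
                             n_samples = 100, transient = TRUE,
                             bout_id = 1L, law_id = 1L,
                             context = c("treadmill", "outdoor")) {
  context <- match.arg(context)
  gen <- function() {
    tmpl <- ankle_template()
    phase <- seq(0, 100, length.out = n_samples + 1)[-(n_samples + 1)]
    th0 <- tmpl(phase)
    dth0 <- tmpl(phase, deriv = 1)            # deg per % phase
    penalty <- metabolic_rate(participant, law, speed, context = context) -
      approx(participant$anchor_speeds, participant$base_rates, xout = speed,
             rule = 2)$y
    # mechanical channel: plantarflexion tracks the torque profile
    mech <- participant$kinematic_gain * torque_at_phase(law, phase)
    dmech <- c(diff(mech), mech[1] - mech[n_samples]) / (100 / n_samples)
    # response channel: push-off extension at toe-off, larger when the
    # assistance is metabolically better (penalty smaller)
    A0 <- participant$response_gain * (0.5 - penalty)
    bump <- late_stance_bump(phase, center = 64, width = 20)
    dbump <- c(diff(bump), bump[1] - bump[n_samples]) / (100 / n_samples)
    periods <- pmax(participant$period_intercept +
                      participant$period_slope * speed +
                      rnorm(n_strides, 0, participant$period_sd), 0.5)
    amps <- A0 + rnorm(n_strides, 0, participant$amp_noise_sd)
    if (transient) {
      i <- seq_len(min(6, n_strides))
      amps[i] <- amps[i] + 5 * exp(-(i - 1) / 2)
    }
    lapply(seq_len(n_strides), function(i) {
      scale_t <- 100 / periods[i]             # % phase per second
      ang <- th0 - mech - amps[i] * bump +
        rnorm(n_samples, 0, participant$sample_noise_sd)
      vel <- (dth0 - dmech - amps[i] * dbump) * scale_t +
        rnorm(n_samples, 0, participant$sample_noise_sd * 10)
      stride_record(ang, vel, periods[i], bout_id = bout_id, law_id = law_id)
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a raw sensor stream with heel-pressure pulses
#'
#' Produces the continuous delimited-text-style stream consumed by
#' [segment_strides()]: uniformly sampled ankle kinematics with a heel
#' pressure channel pulsing at each heel strike. Returns the ground-truth
#' strike times for use as a segmentation oracle.
#'
#' @inheritParams generate_strides
#' @param fs Sampling rate, Hz.
#' @return List with `stream` (data frame) and `strike_times` (seconds).
#' @export
generate_stride_stream <- function(participant, law, speed, n_strides,
                                   seed = NULL, fs = 100, bout_id = 1L,
                                   law_id = 1L) {
  gen <- function() {
    strides <- generate_strides(participant, law, speed, n_strides,
                                n_samples = 50, bout_id = bout_id,
                                law_id = law_id)
    periods <- vapply(strides, function(s) s$stride_period, numeric(1))
    strikes <- cumsum(c(0, periods))
    t_end <- strikes[length(strikes)]
    tt <- seq(0, t_end + 0.2, by = 1 / fs)  # cover the final strike pulse
    idx <- pmin(findInterval(tt, strikes), n_strides)
    ang <- vel <- numeric(length(tt))
    for (i in seq_len(n_strides)) {
      sel <- idx == i & tt < strikes[i + 1]
      ph <- (tt[sel] - strikes[i]) / periods[i]
      src <- seq(0, 1, length.out = 50)
      ang[sel] <- approx(src, strides[[i]]$ankle_angle, xout = ph, rule = 2)$y
      vel[sel] <- approx(src, strides[[i]]$ankle_velocity, xout = ph, rule = 2)$y
    }
    pressure <- numeric(length(tt))
    for (s in strikes) pressure[tt >= s & tt < s + 0.15] <- 1
    pressure <- pressure * runif(length(tt), 0.8, 1.0)
    list(stream = data.frame(time_s = tt, angle_deg = ang, velocity_deg_s = vel,
                             heel_pressure = pressure, bout_id = bout_id,
                             law_id = law_id),
         strike_times = strikes)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate breath-by-breath respirometry from a metabolic power trace
#'
#' True instantaneous metabolic power is passed through a first-order filter
#' (time constant `sensor_tau`, mimicking mitochondrial, transport and
#' respiratory dynamics), inverted to VO2/VCO2 at a fixed respiratory
#' exchange ratio, and sampled at irregular breath intervals with
#' multiplicative noise. The filter conserves the time integral, so with a
#' full recovery window the emitted energy matches the input energy.
#'
#' @param participant A `sim_participant`.
#' @param power_trace True metabolic power, W, uniformly sampled.
#' @param dt Sampling interval of `power_trace`, s.
#' @param seed Optional seed.
#' @param breath_interval Mean breath interval, s.
#' @param noise_cv Coefficient of variation of per-breath gas volumes.
#' @return Data frame with `time_s`, `vo2_ml_min`, `vco2_ml_min`.
#' @export
generate_breaths <- function(participant, power_trace, dt, seed = NULL,
                             breath_interval = 4, noise_cv = 0.03) {
  gen <- function() {
    tau <- participant$sensor_tau
    a <- 1 - exp(-dt / tau)
    y <- numeric(length(power_trace))
    y[1] <- power_trace[1]
    for (i in seq_along(power_trace)[-1])
      y[i] <- y[i - 1] + a * (power_trace[i] - y[i - 1])
    t_end <- (length(power_trace) - 1) * dt
    bt <- cumsum(pmax(rnorm(ceiling(t_end / breath_interval * 2),
                            breath_interval, 0.5), 1))
    bt <- bt[bt <= t_end]
    p_breath <- approx(seq(0, t_end, by = dt), y, xout = bt)$y
    vo2_mls <- p_breath / (16.58 + 4.51 * participant$rer)
    noise <- pmax(rnorm(length(bt), 1, noise_cv), 0)
    data.frame(time_s = bt,
               vo2_ml_min = vo2_mls * 60 * noise,
               vco2_ml_min = vo2_mls * participant$rer * 60 * noise)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a session schedule
#'
#' `treadmill_constant` is one long bout at a fixed speed;
#' `treadmill_sinusoid` varies speed sinusoidally between 0.75 and
#' 1.75 m s^-1 with a 30-s period; `naturalistic` draws bout lengths from a
#' log-normal step distribution (median about 40 steps, 90% under 100) and
#' bout speeds from a mixture placing one-third of bouts in each real-world
#' speed bin, with 5-10 s standing rests between bouts.
#'
#' @param style One of `"treadmill_constant"`, `"treadmill_sinusoid"`,
#'   `"naturalistic"`.
#' @param duration_s Total session duration, s.
#' @param seed Optional seed.
#' @param speed Constant-treadmill speed, m s^-1.
#' @param median_steps Median naturalistic bout length, steps.
#' @return A `session_schedule`: data frame of bouts (`n_steps`,
#'   `target_speed`, `rest_s`) with the style and any sinusoid parameters as
#'   attributes.
#' @export
generate_schedule <- function(style = c("naturalistic", "treadmill_constant",
                                        "treadmill_sinusoid"),
                              duration_s = 3600, seed = NULL, speed = 1.25,
                              median_steps = 40) {
  style <- match.arg(style)
  gen <- function() {
    if (style == "treadmill_constant") {
      steps <- floor(duration_s / (1.475 - 0.3 * speed))
      sch <- data.frame(n_steps = steps, target_speed = speed, rest_s = 0)
    } else if (style == "treadmill_sinusoid") {
      steps <- floor(duration_s / (1.475 - 0.3 * 1.25))
      sch <- data.frame(n_steps = steps, target_speed = 1.25, rest_s = 0)
      attr(sch, "speed_min") <- 0.75
      attr(sch, "speed_max") <- 1.75
      attr(sch, "period_s") <- 30
    } else {
      sdlog <- log(100 / median_steps) / qnorm(0.9)  # 90% of bouts < 100 steps
      bouts <- list()
      t_total <- 0
      while (t_total < duration_s) {
        n <- max(5L, min(300L, round(rlnorm(1, log(median_steps), sdlog))))
        bin <- sample.int(3, 1)
        sp <- switch(bin,
                     min(max(rnorm(1, 1.05, 0.08), 0.80), 1.21),
                     min(max(rnorm(1, 1.30, 0.05), 1.22), 1.38),
                     min(max(rnorm(1, 1.50, 0.08), 1.39), 1.80))
        rest <- runif(1, 5, 10)
        t_total <- t_total + n * (1.475 - 0.3 * sp) + rest
        bouts[[length(bouts) + 1]] <-
          data.frame(n_steps = n, target_speed = sp, rest_s = rest)
      }
      sch <- do.call(rbind, bouts)
    }
    attr(sch, "style") <- style
    class(sch) <- c("session_schedule", "data.frame")
    sch
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
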