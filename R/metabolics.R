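#' Metabolic power of a single breath
#'
#' Standard indirect-calorimetry conversion (Brockway) of breath-by-breath
#' gas exchange to metabolic power:
#' `P = 16.58 * VO2 + 4.51 * VCO2` with rates in ml s^-1 (inputs are the
#' conventional ml min^-1).
#'
#' @param vo2 Oxygen uptake, ml min^-1.
#' @param vco2 Carbon-dioxide output, ml min^-1.
#' @param o2_coef,co2_coef Energy equivalents, W per ml s^-1.
#' @return Metabolic power, W (vectorized).
#' @examples
#' breath_power(300, 250)  # 101.7 W
#' @export
breath_power <- function(vo2, vco2, o2_coef = 16.58, co2_coef = 4.51) {
  if (any(vo2 < 0) || any(vco2 < 0))
    stop("gas exchange rates must be non-negative", call. = FALSE)
  o2_coef * vo2 / 60 + co2_coef * vco2 / 60
}

breath_frame <- function(breaths) {
  need <- c("time_s", "vo2_ml_min", "vco2_ml_min")
  if (!all(need %in% names(breaths)))
    stop("breath data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(diff(breaths$time_s) <= 0))
    stop("breath times must be strictly increasing", call. = FALSE)
  breaths
}

#' Quiet-standing metabolic baseline
#'
#' Mean breath power over a quiet-standing window, normalized to body mass.
#' This baseline is subtracted from all subsequent walking measurements to
#' isolate the cost of walking and remove absolute calibration error.
#'
#' @param breaths Data frame with `time_s`, `vo2_ml_min`, `vco2_ml_min`.
#' @param body_mass Body mass, kg.
#' @param window Optional `c(start, end)` in seconds; defaults to the full
#'   record, which must span at least `min_duration` seconds.
#' @param min_duration Minimum standing duration, seconds (default 120).
#' @return Standing metabolic rate, W kg^-1.
#' @export
standing_baseline <- function(breaths, body_mass, window = NULL,
                              min_duration = 120) {
  breaths <- breath_frame(breaths)
  if (!is.null(window))
    breaths <- breaths[breaths$time_s >= window[1] & breaths$time_s < window[2], ]
  if (nrow(breaths) < 2 || diff(range(breaths$time_s)) < min_duration)
    stop("insufficient data: need at least ", min_duration,
         " s of quiet standing", call. = FALSE)
  mean(breath_power(breaths$vo2_ml_min, breaths$vco2_ml_min)) / body_mass
}

#' Steady-state net metabolic rate of a 6-min condition
#'
#' The steady-state cost of a walking condition is the mean net metabolic
#' power (standing baseline removed) over the last 3 min of the 6-min
#' condition. Windows are closed on the left: a breath at exactly 180 s into
#' the condition is included.
#'
#' @param breaths Breath data frame (see [standing_baseline()]).
#' @param body_mass Body mass, kg.
#' @param baseline Standing baseline, W kg^-1.
#' @param condition_start Condition start time, s (default 0).
#' @param condition_duration Condition duration, s; must be >= 360.
#' @return Net steady-state metabolic rate, W kg^-1.
#' @export
steady_state_rate <- function(breaths, body_mass, baseline,
                              condition_start = 0, condition_duration = 360) {
  if (condition_duration < 360)
    stop("condition must last at least 360 s for a steady-state estimate",
         call. = FALSE)
  breaths <- breath_frame(breaths)
  t0 <- condition_start + condition_duration / 2
  t1 <- condition_start + condition_duration
  sel <- breaths$time_s >= t0 & breaths$time_s < t1
  if (!any(sel)) stop("no breaths in the steady-state window", call. = FALSE)
  mean(breath_power(breaths$vo2_ml_min[sel], breaths$vco2_ml_min[sel])) /
    body_mass - baseline
}

#' Cumulative net metabolic cost of a walking interval
#'
#' Time integral (trapezoidal over the irregular breath times) of net
#' metabolic power over the walking interval plus a recovery window. Because
#' respiratory dynamics delay expired-gas measurements relative to muscular
#' energy use, the excess consumption during recovery is part of the cost of
#' the preceding walking.
#'
#' @param breaths Breath data frame.
#' @param body_mass Body mass, kg.
#' @param baseline Standing baseline, W kg^-1.
#' @param walk_start,walk_end Walking interval, s.
#' @param recovery Recovery window appended after `walk_end`, s (default 180).
#' @return Cumulative net energy, J kg^-1.
#' @export
cumulative_cost <- function(breaths, body_mass, baseline, walk_start, walk_end,
                            recovery = 180) {
  breaths <- breath_frame(breaths)
  t1 <- walk_end + recovery
  if (max(breaths$time_s) < t1)
    stop("truncated recovery: breath data end before walk_end + recovery",
         call. = FALSE)
  sel <- breaths$time_s >= walk_start & breaths$time_s <= t1
  tt <- breaths$time_s[sel]
  p <- breath_power(breaths$vo2_ml_min[sel], breaths$vco2_ml_min[sel]) /
    body_mass - baseline
  pracma::trapz(tt, p)
}

#' Walking speed of a bout and of a whole course
#'
#' Bout speed is the fixed bout distance divided by the time spent walking in
#' that bout. Course speed is total distance over total walking time (not the
#' mean of bout speeds).
#'
#' @param distance Distance walked, m (scalar or per-bout vector).
#' @param walking_time Time spent walking, s (matching length).
#' @return Speed, m s^-1.
#' @export
bout_speed <- function(distance, walking_time) {
  if (any(walking_time <= 0)) stop("walking time must be positive", call. = FALSE)
  distance / walking_time
}

#' @rdname bout_speed
#' @export
course_speed <- function(distance, walking_time) {
  bout_speed(sum(distance), sum(walking_time))
}

#' Percent change of an energetic outcome versus a baseline condition
#'
#' `100 * (condition - baseline) / baseline`; negative values are
#' improvements (lower cost, or, for speed, slower — pick the measure
#' accordingly).
#'
#' @param condition,baseline Measured outcome values (e.g. steady-state rate
#'   in W kg^-1 or cost of transport in J kg^-1 m^-1).
#' @return Percent change.
#' @examples
#' percent_change(1.44, 1.64)  # about -12.2
#' @export
percent_change <- function(condition, baseline) {
  if (any(baseline == 0)) stop("baseline must be nonzero", call. = FALSE)
  100 * (condition - baseline) / baseline
}

#' Summarize the energetics of one walking condition
#'
#' Convenience wrapper combining the steady-state or cumulative measures into
#' the standard outcome set for a condition: net steady rate, cumulative
#' energy including recovery, distance, cost of transport and mean speed.
#'
#' @param breaths Breath data frame covering the condition and recovery.
#' @param body_mass Body mass, kg.
#' @param baseline Standing baseline, W kg^-1.
#' @param walk_start,walk_end Walking interval, s.
#' @param distance Total distance walked, m.
#' @param recovery Recovery window, s.
#' @return A one-row data frame: `steady_rate` (NA unless the condition lasts
#'   6 min), `cumulative_energy`, `distance`, `cost_of_transport`,
#'   `mean_speed`.
#' @export
condition_energetics <- function(breaths, body_mass, baseline, walk_start,
                                 walk_end, distance, recovery = 180) {
  dur <- walk_end - walk_start
  steady <- if (dur >= 360)
    steady_state_rate(breaths, body_mass, baseline, walk_start, dur) else NA_real_
  cum <- cumulative_cost(breaths, body_mass, baseline, walk_start, walk_end,
                         recovery)
  data.frame(steady_rate = steady, cumulative_energy = cum, distance = distance,
             cost_of_transport = cum / distance,
             mean_speed = bout_speed(distance, dur))
}
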