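#' Allowable ranges for the torque control-law parameters
#'
#' The assistance pattern is defined by four parameters: peak torque magnitude
#' (normalized to body mass, Nm kg^-1), peak time, rise time and fall time
#' (all in percent gait cycle). Laboratory optimization tunes all four
#' (`d = 4`); real-world optimization tunes only peak torque and rise time
#' (`d = 2`), with peak time and fall time held fixed.
#'
#' @param d Number of free parameters, 4 (lab) or 2 (real-world).
#' @return A `parameter_bounds` object with `lower`, `upper`, `names` and `d`.
#' @examples
#' parameter_bounds(4)
#' @export
parameter_bounds <- function(d = 4) {
  if (!d %in% c(2L, 4L)) stop("d must be 2 or 4", call. = FALSE)
  if (d == 4) {
    lower <- c(peak_torque = 0,  peak_time = 40, rise_time = 20, fall_time = 10)
    upper <- c(peak_torque = 1,  peak_time = 55, rise_time = 40, fall_time = 20)
  } else {
    lower <- c(peak_torque = 0,  rise_time = 20)
    upper <- c(peak_torque = 1,  rise_time = 40)
  }
  structure(list(lower = lower, upper = upper, names = names(lower), d = as.integer(d)),
            class = "parameter_bounds")
}

#' @export
print.parameter_bounds <- function(x, ...) {
  cat("Parameter bounds (d =", x$d, ")\n")
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Construct an exoskeleton torque control law
#'
#' A control law is one assistance pattern: exoskeleton plantarflexion torque
#' rises smoothly from zero to `peak_torque` over `rise_time` percent of the
#' gait cycle, peaks at `peak_time`, and falls back to zero over `fall_time`.
#'
#' @param peak_torque Peak torque, Nm per kg body mass, in \[0, 1\].
#' @param peak_time Time of peak torque, percent gait cycle, in \[40, 55\].
#' @param rise_time Rise duration, percent gait cycle, in \[20, 40\].
#' @param fall_time Fall duration, percent gait cycle, in \[10, 20\].
#' @param validate Check bounds (default TRUE).
#' @return A `control_law` object.
#' @examples
#' law <- control_law(0.5, 52, 30, 10)
#' torque_at_phase(law, 52)
#' @export
control_law <- function(peak_torque, peak_time, rise_time, fall_time,
                        validate = TRUE) {
  law <- structure(list(peak_torque = unname(peak_torque),
                        peak_time = unname(peak_time),
                        rise_time = unname(rise_time),
                        fall_time = unname(fall_time)),
                   class = "control_law")
  if (validate) {
    b <- parameter_bounds(4)
    v <- law_params(law)
    bad <- which(v < b$lower - 1e-9 | v > b$upper + 1e-9)
    if (length(bad))
      stop("control law parameter out of bounds: ",
           paste(b$names[bad], collapse = ", "), call. = FALSE)
    if (peak_time - rise_time < 0)
      stop("torque onset before heel strike: peak_time - rise_time < 0",
           call. = FALSE)
  }
  law
}

#' @export
print.control_law <- function(x, ...) {
  cat(sprintf(
    "Control law: peak %.3f Nm/kg at %.1f%% (rise %.1f%%, fall %.1f%%)\n",
    x$peak_torque, x$peak_time, x$rise_time, x$fall_time))
  invisible(x)
}

#' @rdname control_law
#' @param law A `control_law`.
#' @export
law_params <- function(law) {
  c(peak_torque = law$peak_torque, peak_time = law$peak_time,
    rise_time = law$rise_time, fall_time = law$fall_time)
}

#' Map a control law to and from the unit hypercube
#'
#' Optimization is performed on parameters normalized to their allowable
#' range, so each component of the normalized vector lies in \[0, 1\].
#' `denormalize_law()` inverts the map; for `d = 2` bounds the fixed peak and
#' fall times must be supplied.
#'
#' @param law A `control_law`.
#' @param bounds A `parameter_bounds` object.
#' @return `normalize_law()`: numeric vector of length `bounds$d` in \[0, 1\].
#' @examples
#' b <- parameter_bounds(4)
#' normalize_law(control_law(0.5, 47.5, 30, 15), b)
#' @export
normalize_law <- function(law, bounds = parameter_bounds(4)) {
  v <- law_params(law)[bounds$names]
  bad <- which(v < bounds$lower - 1e-9 | v > bounds$upper + 1e-9)
  if (length(bad))
    stop("parameter out of bounds: ", paste(bounds$names[bad], collapse = ", "),
         call. = FALSE)
  (v - bounds$lower) / (bounds$upper - bounds$lower)
}

#' @rdname normalize_law
#' @param x Normalized parameter vector of length `bounds$d`.
#' @param peak_time,fall_time Values for the fixed parameters when `d = 2`.
#' @export
denormalize_law <- function(x, bounds = parameter_bounds(4),
                            peak_time = 54.6, fall_time = 10) {
  v <- bounds$lower + x * (bounds$upper - bounds$lower)
  if (bounds$d == 4) {
    control_law(v[["peak_torque"]], v[["peak_time"]], v[["rise_time"]],
                v[["fall_time"]], validate = FALSE)
  } else {
    control_law(v[["peak_torque"]], peak_time, v[["rise_time"]], fall_time,
                validate = FALSE)
  }
}

#' Constrain fall time so no torque is applied after toe-off
#'
#' Fall time is capped at `toe_off - peak_time` so that assistance ends by
#' toe-off and no torque is applied during swing. When the cap falls below the
#' allowable fall-time lower bound (peak times near 55% of the gait cycle),
#' fall time is clamped to that lower bound and the returned law carries a
#' `constraint_clamped` attribute.
#'
#' @param law A `control_law`.
#' @param toe_off Toe-off time, percent gait cycle; 62 is typical for normal
#'   walking speed.
#' @param fall_min Lower bound of the allowable fall-time range.
#' @return The constrained `control_law`.
#' @examples
#' apply_timing_constraint(control_law(0.5, 50, 30, 20), toe_off = 62)
#' @export
apply_timing_constraint <- function(law, toe_off = 62, fall_min = 10) {
  if (toe_off <= law$peak_time)
    stop("infeasible timing constraint: toe_off <= peak_time", call. = FALSE)
  cap <- toe_off - law$peak_time
  new_fall <- min(law$fall_time, cap)
  clamped <- FALSE
  if (new_fall < fall_min) {
    new_fall <- fall_min
    clamped <- TRUE
  }
  out <- law
  out$fall_time <- new_fall
  attr(out, "constraint_clamped") <- clamped
  out
}

#' Evaluate the torque profile of a control law
#'
#' The torque curve is two cubic Hermite (smoothstep) segments: zero to
#' `peak_torque` over the rise interval and back to zero over the fall
#' interval, with zero slope at onset, peak and end. Torque is zero elsewhere
#' in the gait cycle; phase is wrapped modulo 100.
#'
#' @param law A `control_law`.
#' @param phase Gait-cycle phase, percent; any numeric vector.
#' @return Torque in Nm kg^-1, same length as `phase`.
#' @examples
#' torque_at_phase(control_law(0.8, 50, 25, 12), c(0, 40, 50, 60, 80))
#' @export
torque_at_phase <- function(law, phase) {
  p <- phase %% 100
  onset <- law$peak_time - law$rise_time
  end <- law$peak_time + law$fall_time
  tau <- numeric(length(p))
  smooth <- function(s) s * s * (3 - 2 * s)
  up <- p >= onset & p < law$peak_time
  if (law$rise_time > 0 && any(up))
    tau[up] <- law$peak_torque * smooth((p[up] - onset) / law$rise_time)
  dn <- p >= law$peak_time & p <= end
  if (law$fall_time > 0 && any(dn))
    tau[dn] <- law$peak_torque * smooth((end - p[dn]) / law$fall_time)
  tau
}

#' @rdname torque_at_phase
#' @param n Number of evenly spaced phase samples on \[0, 100).
#' @return `torque_profile()`: a data frame with columns `phase` and `torque`.
#' @export
torque_profile <- function(law, n = 1000) {
  phase <- seq(0, 100, length.out = n + 1)[-(n + 1)]
  data.frame(phase = phase, torque = torque_at_phase(law, phase))
}

#' The zero-torque assistance condition
#'
#' A control law whose profile is identically zero: the exoskeleton is worn
#' but provides no assistive torque. Used as an experimental baseline.
#'
#' @return A `control_law` with zero peak torque.
#' @export
zero_torque_law <- function() control_law(0, 50, 30, 10)

#' The generic assistance parameters
#'
#' Group-average optimized parameters used to initialize optimization and as a
#' non-personalized comparison condition.
#'
#' @return A `control_law`.
#' @export
generic_law <- function() control_law(0.5, 52, 30, 10)
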