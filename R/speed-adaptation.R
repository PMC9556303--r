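#' Fit the stride-period to walking-speed model
#'
#' Ordinary least squares of walking speed on stride period from a short
#' calibration walk. Over the calibration range longer stride periods
#' correspond to slower walking, so the slope is negative.
#'
#' @param periods Stride periods, seconds.
#' @param speeds Known walking speeds, m s^-1.
#' @return A `speed_model` with `intercept`, `slope`, fitted residuals and
#'   their RMSE.
#' @export
fit_speed_model <- function(periods, speeds) {
  if (length(unique(periods)) < 2)
    stop("rank-deficient calibration: need at least two distinct stride periods",
         call. = FALSE)
  fit <- lm(speeds ~ periods)
  structure(list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                 residuals = unname(fit$residuals),
                 rmse = sqrt(mean(fit$residuals^2))),
            class = "speed_model")
}

#' @export
print.speed_model <- function(x, ...) {
  cat(sprintf("Speed model: speed = %.3f + %.3f * period (RMSE %.3f m/s)\n",
              x$intercept, x$slope, x$rmse))
  invisible(x)
}

#' Estimate walking speed from a stride period
#'
#' @param model A `speed_model`.
#' @param stride_period Stride period(s), seconds; must be positive.
#' @return Estimated speed(s), m s^-1, floored at zero (a `floored` attribute
#'   flags any floored estimates).
#' @export
estimate_speed <- function(model, stride_period) {
  if (any(stride_period <= 0)) stop("stride period must be positive", call. = FALSE)
  v <- model$intercept + model$slope * stride_period
  floored <- v < 0
  v <- pmax(v, 0)
  attr(v, "floored") <- any(floored)
  v
}

#' Per-speed optimized parameter anchors
#'
#' @param speeds Strictly increasing anchor speeds, m s^-1 (defaults to the
#'   three optimization speeds 0.75, 1.25 and 1.75).
#' @param laws List of `control_law`s, one per anchor speed.
#' @return A `speed_anchors` object.
#' @export
speed_anchors <- function(laws, speeds = c(0.75, 1.25, 1.75)) {
  if (length(laws) != length(speeds) || length(speeds) < 2)
    stop("need one law per anchor speed and at least two anchors", call. = FALSE)
  if (any(diff(speeds) <= 0))
    stop("anchor speeds must be strictly increasing", call. = FALSE)
  structure(list(speeds = speeds, laws = laws), class = "speed_anchors")
}

#' Expected stance fraction at a walking speed
#'
#' Toe-off comes earlier in the gait cycle at faster speeds. The expected
#' stance fraction is adjusted linearly from 62% at 1.25 m s^-1 with a
#' configurable slope; used to set the toe-off time for the torque timing
#' constraint.
#'
#' @param speed Walking speed, m s^-1.
#' @param at_ref Stance fraction at the reference speed (default 0.62).
#' @param ref_speed Reference speed (default 1.25 m s^-1).
#' @param slope Change in stance fraction per m s^-1 (default -0.03).
#' @return Stance fraction in (0, 1).
#' @export
stance_fraction <- function(speed, at_ref = 0.62, ref_speed = 1.25,
                            slope = -0.03) {
  pmin(pmax(at_ref + slope * (speed - ref_speed), 0.45), 0.75)
}

#' Interpolate optimized assistance parameters at a walking speed
#'
#' Each torque parameter is piecewise-linearly interpolated between the
#' bracketing anchor speeds and clamped to the end anchors outside the
#' calibrated range; the toe-off timing constraint is applied at the
#' speed-dependent toe-off time.
#'
#' @param anchors A `speed_anchors`.
#' @param speed Walking speed, m s^-1.
#' @return A `control_law`.
#' @export
interpolate_law <- function(anchors, speed) {
  P <- vapply(anchors$laws, law_params, numeric(4))
  v <- apply(P, 1, function(p)
    approx(anchors$speeds, p, xout = speed, rule = 2)$y)
  law <- control_law(v[["peak_torque"]], v[["peak_time"]], v[["rise_time"]],
                     v[["fall_time"]], validate = FALSE)
  apply_timing_constraint(law, toe_off = 100 * stance_fraction(speed))
}

#' Select the assistance for the next step from the previous stride period
#'
#' Speed-adaptive control is causal with a one-step lag: the walking speed
#' estimated from the previous step selects the parameters applied on the
#' following step. Before any stride has been observed the middle anchor's
#' law is used (flagged via the `fallback` attribute).
#'
#' @param anchors A `speed_anchors`.
#' @param model A `speed_model`.
#' @param previous_stride_period Previous stride period in seconds, or `NULL`
#'   at the start of a session.
#' @return A `control_law`.
#' @export
next_step_law <- function(anchors, model, previous_stride_period = NULL) {
  if (is.null(previous_stride_period)) {
    law <- anchors$laws[[ceiling(length(anchors$laws) / 2)]]
    attr(law, "fallback") <- TRUE
    return(law)
  }
  interpolate_law(anchors, as.numeric(estimate_speed(model, previous_stride_period)))
}
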