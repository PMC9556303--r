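#' Construct a single stride record
#'
#' One heel-strike-to-heel-strike interval of ankle kinematics. Trajectories
#' are assumed uniformly sampled over the stride.
#'
#' @param ankle_angle Ankle angle samples, degrees (dorsiflexion positive).
#' @param ankle_velocity Ankle angular velocity samples, degrees s^-1.
#' @param stride_period Stride duration, seconds.
#' @param bout_id,law_id Identifiers for the walking bout and active control law.
#' @return A `stride_record`.
#' @export
stride_record <- function(ankle_angle, ankle_velocity, stride_period,
                          bout_id = 1L, law_id = 1L) {
  if (length(ankle_angle) != length(ankle_velocity))
    stop("angle and velocity trajectories must share sample count", call. = FALSE)
  if (length(ankle_angle) < 30)
    stop("stride trajectories need at least 30 samples", call. = FALSE)
  if (stride_period <= 0) stop("stride_period must be positive", call. = FALSE)
  structure(list(ankle_angle = ankle_angle, ankle_velocity = ankle_velocity,
                 stride_period = stride_period, bout_id = bout_id,
                 law_id = law_id),
            class = "stride_record")
}

#' Segment a continuous sensor stream into strides
#'
#' Strides are cut at heel strikes, detected as the heel-pressure channel
#' rising across a threshold (a fraction of the per-bout maximum pressure)
#' with a refractory period that suppresses double triggers. Each
#' inter-strike interval becomes one [stride_record()]; its period is the
#' inter-strike time.
#'
#' @param stream Data frame with columns `time_s`, `angle_deg`,
#'   `velocity_deg_s`, `heel_pressure`, and optionally `bout_id`, `law_id`.
#' @param threshold_frac Detection threshold as a fraction of the per-bout
#'   maximum heel pressure.
#' @param refractory_s Minimum time between detected strikes, seconds.
#' @return List of `stride_record`s (empty, with a warning, if fewer than two
#'   heel strikes are found).
#' @export
segment_strides <- function(stream, threshold_frac = 0.2, refractory_s = 0.2) {
  need <- c("time_s", "angle_deg", "velocity_deg_s", "heel_pressure")
  if (!all(need %in% names(stream)))
    stop("stream must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(stream$bout_id)) stream$bout_id <- 1L
  if (is.null(stream$law_id)) stream$law_id <- 1L
  out <- list()
  for (b in unique(stream$bout_id)) {
    sb <- stream[stream$bout_id == b, , drop = FALSE]
    thr <- threshold_frac * max(sb$heel_pressure)
    if (thr <= 0) next
    above <- sb$heel_pressure >= thr
    rising <- which(above & !c(FALSE, above[-length(above)]))
    if (length(rising) > 1) {       # enforce refractory period
      keep <- rising[1]
      for (i in rising[-1])
        if (sb$time_s[i] - sb$time_s[keep[length(keep)]] >= refractory_s)
          keep <- c(keep, i)
      rising <- keep
    }
    if (length(rising) < 2) next
    for (k in seq_len(length(rising) - 1)) {
      idx <- rising[k]:(rising[k + 1] - 1)
      out[[length(out) + 1]] <- stride_record(
        sb$angle_deg[idx], sb$velocity_deg_s[idx],
        sb$time_s[rising[k + 1]] - sb$time_s[rising[k]],
        bout_id = b, law_id = sb$law_id[idx[1]])
    }
  }
  if (!length(out)) warning("no heel strikes detected; returning empty stride set")
  out
}

#' Discard early adaptation strides
#'
#' The first strides under a new control law show fast kinematic adaptation
#' and are discarded before feature extraction.
#'
#' @param strides List of `stride_record`s from one control-law evaluation.
#' @param n_adapt Number of leading strides to drop (default 6).
#' @return The remaining strides, order preserved.
#' @export
discard_adaptation <- function(strides, n_adapt = 6) {
  if (length(strides) <= n_adapt)
    stop("insufficient data: need more than ", n_adapt, " strides, got ",
         length(strides), call. = FALSE)
  strides[-seq_len(n_adapt)]
}

bin_trajectory <- function(x, n_bins = 30) {
  # within-bin mean over equal-width, half-open phase bins [b, b+1)*(100/n_bins)
  m <- length(x)
  bin <- pmin(floor(seq(0, m - 1) / m * n_bins) + 1, n_bins)
  as.numeric(tapply(x, factor(bin, levels = seq_len(n_bins)), mean))
}

#' Build the 64-value condition feature vector
#'
#' Each stride's angle and velocity trajectories are averaged within 30
#' equal-width gait-phase bins; bins are then averaged across strides (equal
#' stride weights). The four control-law parameters, in physical units, are
#' appended, giving a vector of exactly 64 values.
#'
#' @param strides List of `stride_record`s (post adaptation discard).
#' @param law The `control_law` active during those strides.
#' @param n_bins Number of phase bins (default 30).
#' @return A `condition_features` object; `$vector` has length
#'   `2 * n_bins + 4`.
#' @export
bin_condition <- function(strides, law, n_bins = 30) {
  if (!length(strides)) stop("insufficient data: empty stride set", call. = FALSE)
  ang <- rowMeans(vapply(strides, function(s) bin_trajectory(s$ankle_angle, n_bins),
                         numeric(n_bins)))
  vel <- rowMeans(vapply(strides, function(s) bin_trajectory(s$ankle_velocity, n_bins),
                         numeric(n_bins)))
  tp <- law_params(law)
  vec <- c(setNames(ang, paste0("angle_b", seq_len(n_bins))),
           setNames(vel, paste0("velocity_b", seq_len(n_bins))), tp)
  structure(list(angle_bins = ang, velocity_bins = vel, torque_params = tp,
                 vector = vec, n_strides = length(strides)),
            class = "condition_features")
}

#' @export
print.condition_features <- function(x, ...) {
  cat(sprintf("Condition features: %d values from %d strides\n",
              length(x$vector), x$n_strides))
  invisible(x)
}

#' Pairwise feature difference between two conditions
#'
#' The classifier input for a pair of control laws is the elementwise
#' difference of their condition feature vectors, so
#' `feature_delta(a, b)$delta == -feature_delta(b, a)$delta`.
#'
#' @param a,b `condition_features` objects (or bare length-64 vectors).
#' @param pair Optional ordered pair of law identifiers.
#' @return A `feature_delta` with fields `delta` and `pair`.
#' @export
feature_delta <- function(a, b, pair = c(1L, 2L)) {
  va <- if (inherits(a, "condition_features")) a$vector else a
  vb <- if (inherits(b, "condition_features")) b$vector else b
  if (length(va) != length(vb))
    stop("feature vectors differ in length: ", length(va), " vs ", length(vb),
         call. = FALSE)
  structure(list(delta = va - vb, pair = pair), class = "feature_delta")
}
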