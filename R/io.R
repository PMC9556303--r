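#' Read and write the delimited stride-stream format
#'
#' One row per sensor sample: `time_s`, `angle_deg`, `velocity_deg_s`,
#' `heel_pressure`, `bout_id`, `law_id`. A comment header line carries the
#' generating seed when one is recorded.
#'
#' @param stream Stride-stream data frame.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @return `read_stride_stream()` returns the data frame (seed, if present,
#'   as the `seed` attribute).
#' @export
write_stride_stream <- function(stream, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.csv(stream, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stride_stream
#' @export
read_stride_stream <- function(path) {
  first <- readLines(path, n = 1)
  seed <- if (startsWith(first, "# seed:"))
    as.integer(sub("# seed:\\s*", "", first)) else NULL
  out <- read.csv(path, comment.char = "#")
  attr(out, "seed") <- seed
  out
}

#' @rdname write_stride_stream
#' @param breaths Breath data frame (`time_s`, `vo2_ml_min`, `vco2_ml_min`).
#' @export
write_breaths <- function(breaths, path, seed = NULL) {
  write_stride_stream(breaths, path, seed)
}

#' @rdname write_stride_stream
#' @export
read_breaths <- function(path) read_stride_stream(path)

#' Serialize a control law to structured text
#'
#' @param law A `control_law`.
#' @param path File path (YAML).
#' @param body_mass Optional body mass, kg, stored alongside the
#'   mass-normalized parameters.
#' @return `read_control_law()` returns the `control_law` (body mass, if
#'   stored, as the `body_mass` attribute).
#' @export
write_control_law <- function(law, path, body_mass = NULL) {
  rec <- c(as.list(law_params(law)),
           if (!is.null(body_mass)) list(body_mass = body_mass))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_control_law
#' @export
read_control_law <- function(path) {
  rec <- yaml::read_yaml(path)
  law <- control_law(rec$peak_torque, rec$peak_time, rec$rise_time,
                     rec$fall_time)
  attr(law, "body_mass") <- rec$body_mass
  law
}

#' Serialize classifier weights as a named two-column table
#'
#' @param classifier An `exo_classifier`.
#' @param path File path (tab-delimited text).
#' @return `read_classifier()` reconstructs the `exo_classifier`.
#' @export
write_classifier <- function(classifier, path) {
  df <- data.frame(feature = names(classifier$W), weight = unname(classifier$W))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lambda: %g", classifier$lambda), con)
  writeLines(sprintf("# n_pairs: %d", classifier$n_pairs), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  hdr <- readLines(path, n = 2)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(list(W = setNames(df$weight, df$feature),
                 lambda = as.numeric(sub("# lambda:\\s*", "", hdr[1])),
                 n_pairs = as.integer(sub("# n_pairs:\\s*", "", hdr[2]))),
            class = "exo_classifier")
}

#' Checkpoint an optimizer state to structured text
#'
#' Everything needed to resume a session mid-protocol: mean, covariance,
#' step size, evolution paths and generation counter.
#'
#' @param state A `cmaes_state`.
#' @param path File path (YAML).
#' @return `read_optimizer_state()` reconstructs the `cmaes_state` (any
#'   pending plan is not preserved; re-ask after resuming).
#' @export
write_optimizer_state <- function(state, path) {
  # full double precision so a resumed session continues bit-for-bit
  yaml::write_yaml(list(
    d = state$d, k = state$k, mean = as.numeric(state$mean),
    C = as.numeric(state$C), sigma = state$sigma, sigma0 = state$sigma0,
    ps = as.numeric(state$ps), pc = as.numeric(state$pc),
    generation = state$generation), path, precision = 15L)
  invisible(path)
}

#' @rdname write_optimizer_state
#' @param bounds `parameter_bounds` matching the checkpointed dimension.
#' @export
read_optimizer_state <- function(path, bounds = NULL) {
  rec <- yaml::read_yaml(path)
  if (is.null(bounds)) bounds <- parameter_bounds(rec$d)
  st <- init_optimizer(rep(0.5, rec$d), bounds, sigma = rec$sigma, k = rec$k)
  st$mean <- as.numeric(rec$mean)
  st$C <- matrix(as.numeric(rec$C), rec$d, rec$d)
  st$sigma0 <- rec$sigma0
  st$ps <- as.numeric(rec$ps)
  st$pc <- as.numeric(rec$pc)
  st$generation <- as.integer(rec$generation)
  st
}

#' Serialize per-speed anchor laws
#'
#' @param anchors A `speed_anchors`.
#' @param path File path (YAML).
#' @return `read_speed_anchors()` reconstructs the object.
#' @export
write_speed_anchors <- function(anchors, path) {
  yaml::write_yaml(lapply(seq_along(anchors$speeds), function(i)
    c(list(speed = anchors$speeds[i]), as.list(law_params(anchors$laws[[i]])))),
    path)
  invisible(path)
}

#' @rdname write_speed_anchors
#' @export
read_speed_anchors <- function(path) {
  recs <- yaml::read_yaml(path)
  speed_anchors(
    lapply(recs, function(r) control_law(r$peak_torque, r$peak_time,
                                         r$rise_time, r$fall_time)),
    speeds = vapply(recs, `[[`, numeric(1), "speed"))
}

#' Load and validate an experiment configuration
#'
#' YAML configuration holding the bounds dimension, anchor speeds, bin
#' boundaries, optimizer constants and simulator parameters. Unknown keys
#' are rejected; defaults fill anything omitted.
#'
#' @param path YAML file path (NULL for the defaults).
#' @return A named list of validated settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(d = 4, sigma = 0.1, generations = 8, eval_seconds = 30,
                   speed = 1.25, anchor_speeds = c(0.75, 1.25, 1.75),
                   bin_boundaries = c(1.22, 1.38), fixed_peak_time = 54.6,
                   fixed_fall_time = 10, toe_off = 62, duration_s = 3600,
                   n_participants = 5, n_conditions = 160, body_mass = 67)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("invalid config: unknown keys ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, user)
}
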