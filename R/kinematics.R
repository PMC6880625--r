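# Trajectory-derived kinematic measures.
#
# All measures are computed on the raw timestamped samples; the 101-timestep
# time normalization is provided for export and plotting but deliberately not
# used for velocity or distance (resampling distorts both).

#' Time-normalize a trajectory to a fixed number of steps
#'
#' Resamples a trajectory at `n_steps` equally spaced times spanning the
#' recorded interval, with positions linearly interpolated. The first and last
#' positions are preserved exactly.
#'
#' @param traj A [trajectory()] (or coercible object) with at least 2 samples.
#' @param n_steps Number of output samples (default 101).
#' @return A new `sst_trajectory` of length `n_steps`.
#' @export
resample_trajectory <- function(traj, n_steps = 101L) {
  traj <- as_trajectory(traj)
  n <- length(traj$t_ms)
  if (n < 2L) stop("resampling requires at least 2 samples", call. = FALSE)
  stopifnot(is_count(n_steps), n_steps >= 2)
  tt <- seq(traj$t_ms[1], traj$t_ms[n], length.out = n_steps)
  x <- stats::approx(traj$t_ms, traj$x, xout = tt, ties = "ordered")$y
  y <- stats::approx(traj$t_ms, traj$y, xout = tt, ties = "ordered")$y
  # guard endpoints against floating-point drift in seq()
  x[1] <- traj$x[1]; y[1] <- traj$y[1]
  x[n_steps] <- traj$x[n]; y[n_steps] <- traj$y[n]
  trajectory(tt, x, y, sample_interval_ms = diff(tt[1:2]))
}

# Euclidean lengths of the segments between consecutive samples.
segment_lengths <- function(traj) {
  n <- length(traj$t_ms)
  if (n < 2L) return(numeric(0))
  sqrt(diff(traj$x)^2 + diff(traj$y)^2)
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive samples. A motionless
#' interval contributes zero; a single-sample (or empty) trajectory has total
#' distance zero.
#'
#' @param traj A trajectory.
#' @return Path length in screen units.
#' @export
total_distance <- function(traj) {
  sum(segment_lengths(as_trajectory(traj)))
}

#' Maximum cursor speed
#'
#' The maximum over consecutive sample pairs of segment distance divided by
#' the recorded time difference (converted to seconds).
#'
#' @param traj A trajectory with at least 2 samples.
#' @return Speed in screen units per second.
#' @export
max_velocity <- function(traj) {
  traj <- as_trajectory(traj)
  if (length(traj$t_ms) < 2L) stop("max_velocity requires >= 2 samples", call. = FALSE)
  dt <- diff(traj$t_ms) / 1000
  if (any(dt == 0)) stop("duplicate timestamps in trajectory", call. = FALSE)
  max(segment_lengths(traj) / dt)
}

#' Maximum change in cursor speed
#'
#' Per-segment speeds are computed as in [max_velocity()]; the result is the
#' maximum over adjacent segment pairs of the absolute speed difference
#' divided by the time between segment midpoints.
#'
#' @param traj A trajectory with at least 3 samples.
#' @return Acceleration magnitude in screen units per second squared.
#' @export
max_acceleration <- function(traj) {
  traj <- as_trajectory(traj)
  n <- length(traj$t_ms)
  if (n < 3L) stop("max_acceleration requires >= 3 samples", call. = FALSE)
  dt <- diff(traj$t_ms) / 1000
  if (any(dt == 0)) stop("duplicate timestamps in trajectory", call. = FALSE)
  v <- segment_lengths(traj) / dt
  mid <- (traj$t_ms[-n] + traj$t_ms[-1]) / 2000  # segment midpoints, s
  max(abs(diff(v)) / diff(mid))
}

#' Stopping distance of a stop trial
#'
#' The path length traveled after stop-signal onset:
#' `delta = d_total - d_before`, where `d_before` is the path length up to the
#' signal. The segment straddling the signal is split by linear interpolation
#' at exactly `stop_signal_time_ms`. A signal after the last sample yields 0.
#'
#' @param traj The trial's trajectory.
#' @param stop_signal_time_ms Stop-signal onset, ms from stimulus onset.
#' @return Stopping distance in screen units (non-negative).
#' @export
stopping_distance <- function(traj, stop_signal_time_ms) {
  traj <- as_trajectory(traj)
  n <- length(traj$t_ms)
  if (n < 2L) return(0)
  seg <- segment_lengths(traj)
  t0 <- traj$t_ms[-n]
  t1 <- traj$t_ms[-1]
  ts <- stop_signal_time_ms
  if (ts >= traj$t_ms[n]) return(0)
  if (ts <= traj$t_ms[1]) return(sum(seg))
  # fraction of each segment falling after the signal
  frac_after <- clamp((t1 - ts) / (t1 - t0), 0, 1)
  max(sum(seg * frac_after), 0)
}

#' Average stopping distance across SSD levels
#'
#' The mean stopping distance is computed within each stop-signal-delay level
#' first; the result is the unweighted mean of those per-level means
#' (`delta_average`).
#'
#' @param per_trial Data frame (or list coercible to one) with columns
#'   `ssd_ms` and `delta`.
#' @return Average stopping distance in screen units.
#' @export
average_stopping_distance <- function(per_trial) {
  per_trial <- as.data.frame(per_trial)
  if (nrow(per_trial) == 0L) stop("no stop trials supplied", call. = FALSE)
  stopifnot(all(c("ssd_ms", "delta") %in% names(per_trial)))
  means <- tapply(per_trial$delta, per_trial$ssd_ms, mean)
  mean(means)
}

#' Movement initiation time
#'
#' Time (relative to stimulus onset) of the first sample whose cumulative
#' path distance from the start position exceeds `move_threshold`.
#'
#' @param traj The trial's trajectory.
#' @param onset_ms Stimulus onset on the trajectory clock (default 0).
#' @param move_threshold Cumulative displacement threshold in screen units.
#' @return Initiation time in ms, or `NA` if the threshold is never exceeded.
#' @export
movement_initiation_time <- function(traj, onset_ms = 0, move_threshold = 0.01) {
  traj <- as_trajectory(traj)
  if (length(traj$t_ms) < 2L) return(NA_real_)
  cum <- cumsum(segment_lengths(traj))
  i <- which(cum > move_threshold)
  if (length(i) == 0L) return(NA_real_)
  traj$t_ms[i[1] + 1L] - onset_ms
}

#' Movement time
#'
#' Time between movement initiation and the response click (or the end of the
#' trial when no click occurred).
#'
#' @param initiation_ms Movement initiation time, ms.
#' @param response_or_end_ms Click time or trial end, ms.
#' @return Duration in ms (non-negative).
#' @export
movement_time <- function(initiation_ms, response_or_end_ms) {
  out <- response_or_end_ms - initiation_ms
  if (any(!is.na(out) & out < 0)) {
    stop("movement time is negative: inconsistent timestamps", call. = FALSE)
  }
  out
}

#' Kinematic features of one trial
#'
#' Convenience wrapper computing every trajectory measure for a single trial.
#'
#' @param traj The trial's trajectory.
#' @param stop_signal_time_ms Stop-signal onset in ms, or `NA` for go trials.
#' @param response_or_end_ms Click time or trial end, ms (for movement time).
#' @param move_threshold Initiation threshold in screen units.
#' @return A one-row data frame with `total_distance`, `max_velocity`,
#'   `max_acceleration`, `stopping_distance`, `initiation_time_ms`,
#'   `movement_time_ms`.
#' @export
trial_kinematics <- function(traj, stop_signal_time_ms = NA,
                             response_or_end_ms = NA, move_threshold = 0.01) {
  traj <- as_trajectory(traj)
  n <- length(traj$t_ms)
  init <- movement_initiation_time(traj, move_threshold = move_threshold)
  data.frame(
    total_distance = total_distance(traj),
    max_velocity = if (n >= 2) max_velocity(traj) else 0,
    max_acceleration = if (n >= 3) max_acceleration(traj) else 0,
    stopping_distance = if (is.na(stop_signal_time_ms)) NA_real_ else
      stopping_distance(traj, stop_signal_time_ms),
    initiation_time_ms = init,
    movement_time_ms = if (is.na(init) || is.na(response_or_end_ms)) NA_real_ else
      movement_time(init, response_or_end_ms)
  )
}
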