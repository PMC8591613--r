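# Simulated 6-DOF head motion and optical-marker trajectories.

new_rigid_body_trajectory <- function(time, translation, rotation, rate) {
  out <- tibble(
    time = time,
    x = translation[, 1], y = translation[, 2], z = translation[, 3],
    pitch = rotation[, 1], yaw = rotation[, 2], roll = rotation[, 3]
  )
  attr(out, "rate") <- rate
  class(out) <- c("rigid_body_trajectory", class(out))
  out
}

dof_names <- c("x", "y", "z", "pitch", "yaw", "roll")

#' Simulate smooth large-amplitude 6-DOF head motion
#'
#' Generates a band-limited random pose series emulating a standing
#' participant continuously moving and rotating their head. Each degree of
#' freedom is white noise low-pass filtered (zero phase) at
#' `smoothness_cutoff`, shifted to start at the identity pose, and scaled so
#' its realised range matches the requested range. The resulting histograms
#' are approximately symmetric about the start pose.
#'
#' The default ranges emulate the moving condition of a standing adult:
#' roughly 1.0 / 0.5 / 1.15 m of right-left / down-up / back-forward
#' translation and 110 / 150 / 180 degrees of pitch / yaw / roll over the
#' course of a recording.
#'
#' @param duration seconds.
#' @param rate sampling rate, Hz (native motion-capture rate is 120 Hz).
#' @param translation_range length-3 vector of requested per-axis ranges
#'   (max minus min), metres, order (x, y, z) = (right-left, down-up,
#'   back-forward).
#' @param rotation_range length-3 vector of requested ranges in degrees,
#'   order (pitch, yaw, roll).
#' @param smoothness_cutoff low-pass cutoff of the pose series, Hz.
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @return A `rigid_body_trajectory` tibble with columns `time`, `x`, `y`,
#'   `z` (metres) and `pitch`, `yaw`, `roll` (degrees, unwrapped).
#' @export
simulate_motion <- function(duration, rate = 120,
                            translation_range = c(1.0, 0.5, 1.15),
                            rotation_range = c(110, 150, 180),
                            smoothness_cutoff = 1, seed = 1L) {
  stopifnot_scalar_pos(duration, "duration")
  if (rate <= 2 * smoothness_cutoff) {
    abort("`rate` must exceed twice `smoothness_cutoff`.")
  }
  n <- max(2L, round(duration * rate))
  time <- (seq_len(n) - 1) / rate
  ranges <- c(translation_range, rotation_range)
  pose <- matrix(0, n, 6)
  # Band-limited Gaussian noise built in the frequency domain (stationary,
  # no filter edge transients). The envelope rolls off steeply (8th-order
  # magnitude) because real head kinematics carry no measurable power far
  # above their movement bandwidth, and against nanoTesla-scale room fields
  # even -100 dB spectral skirts in the pose would masquerade as
  # higher-frequency magnetic interference.
  noise <- withr::with_seed(seed, matrix(rnorm(n * 6), n, 6))
  f <- (seq_len(n) - 1) * rate / n
  f_fold <- pmin(f, rate - f)
  H <- 1 / sqrt(1 + (f_fold / smoothness_cutoff)^16)
  smooth <- Re(mvfft(mvfft(noise) * H, inverse = TRUE)) / n
  for (j in 1:6) {
    if (ranges[j] <= 0) next
    s <- smooth[, j] - smooth[1, j]
    realised <- diff(range(s))
    if (realised > 0) s <- s * (ranges[j] / realised)
    # keep pitch inside the principal Euler branch: |pitch| >= 90 deg makes
    # the yaw-pitch-roll parameterisation ambiguous
    if (j == 4 && max(abs(s)) > 85) s <- s * (85 / max(abs(s)))
    pose[, j] <- s
  }
  new_rigid_body_trajectory(time, pose[, 1:3, drop = FALSE],
                            pose[, 4:6, drop = FALSE], rate)
}

#' Constant-velocity straight-line trajectory
#'
#' A degenerate pose series useful for kinematic sanity checks: the head
#' translates at constant speed along a fixed direction with no rotation.
#'
#' @param duration seconds.
#' @param rate Hz.
#' @param velocity speed in metres per second.
#' @param direction 3-vector translation direction (normalised internally).
#' @return A `rigid_body_trajectory`.
#' @export
constant_velocity_trajectory <- function(duration, rate = 120, velocity = 0.1,
                                         direction = c(1, 0, 0)) {
  n <- max(2L, round(duration * rate))
  time <- (seq_len(n) - 1) / rate
  d <- normalize3(direction)
  new_rigid_body_trajectory(time, outer(time * velocity, d),
                            matrix(0, n, 3), rate)
}

#' Default rigid-body marker layout
#'
#' Six retro-reflective markers fixed to the sensor helmet, in head-frame
#' coordinates (metres). The layout is non-coplanar and asymmetric so that
#' the rigid-body pose is uniquely determined by any three markers.
#'
#' @return A 6 x 3 matrix.
#' @export
default_marker_layout <- function() {
  rbind(
    c( 0.065, 0.080,  0.035),
    c(-0.070, 0.075,  0.030),
    c( 0.075, 0.040, -0.060),
    c(-0.060, 0.050, -0.075),
    c( 0.000, 0.115,  0.070),
    c( 0.010, 0.120, -0.040)
  )
}

new_marker_trajectories <- function(time, positions, rate, layout) {
  structure(list(time = time, positions = positions, rate = rate,
                 layout = layout),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  miss <- mean(is.na(x$positions[, , 1]))
  cat(sprintf("<marker_trajectories> %d frames x %d markers at %g Hz (%.2f%% occluded)\n",
              length(x$time), dim(x$positions)[2], x$rate, 100 * miss))
  invisible(x)
}

#' Simulate optical-tracker marker trajectories with occlusion gaps
#'
#' Applies each pose of a rigid-body trajectory to a fixed marker layout and
#' then knocks out samples in per-marker, independently placed occlusion
#' gaps. Gap durations are drawn from an exponential distribution with the
#' requested mean, truncated at the requested maximum; gaps are placed until
#' the requested occluded fraction is reached per marker.
#'
#' @param traj a `rigid_body_trajectory`.
#' @param layout marker layout, >= 3 non-collinear rows x 3 (metres, head
#'   frame).
#' @param occlusion length-3 vector `c(fraction, mean_s, max_s)`: target
#'   occluded fraction of samples, mean gap duration (s), maximum gap
#'   duration (s). `c(0, ...)` disables occlusion.
#' @param seed integer seed.
#' @return A `marker_trajectories` object: `time`, `positions` (frames x
#'   markers x 3, `NA` when occluded), `rate`, `layout`.
#' @export
simulate_markers <- function(traj, layout = default_marker_layout(),
                             occlusion = c(0, 0.029, 1.24), seed = 1L) {
  layout <- as.matrix(layout)
  if (nrow(layout) < 3 || qr(sweep(layout, 2, colMeans(layout)))$rank < 2) {
    abort("Marker layout must contain at least 3 non-collinear points.",
          class = "opmpipe_degenerate_rigid_body")
  }
  n <- nrow(traj)
  m <- nrow(layout)
  Rser <- rotation_ypr_series(traj$yaw, traj$pitch, traj$roll)
  Tr <- cbind(traj$x, traj$y, traj$z)
  positions <- array(NA_real_, c(n, m, 3))
  for (k in seq_len(m)) {
    positions[, k, ] <- rotate_series(Rser, layout[k, ]) + Tr
  }
  frac <- occlusion[1]
  if (frac > 0) {
    rate <- attr(traj, "rate")
    mean_len <- max(1, round(occlusion[2] * rate))
    max_len <- max(1, round(occlusion[3] * rate))
    withr::with_seed(seed, {
      for (k in seq_len(m)) {
        occluded <- rep(FALSE, n)
        target <- frac * n
        tries <- 0L
        while (sum(occluded) < target && tries < 50 * n) {
          tries <- tries + 1L
          len <- min(max_len, max(1L, ceiling(stats::rexp(1, 1 / mean_len))))
          start <- sample.int(n - len + 1L, 1L)
          idx <- start:(start + len - 1L)
          if (any(occluded[idx])) next
          occluded[idx] <- TRUE
        }
        positions[occluded, k, ] <- NA_real_
      }
    })
  }
  new_marker_trajectories(traj$time, positions, attr(traj, "rate"), layout)
}

#' Tidy a marker-trajectory object into the motion-capture CSV dialect
#'
#' One row per frame: `frame`, `time_s`, then `M<k>_x`, `M<k>_y`, `M<k>_z`
#' per marker in metres; occluded samples are `NA` (written as blank cells by
#' [write_mocap_csv()]).
#'
#' @param x a `marker_trajectories` object.
#' @param ... unused.
#' @return A tibble.
#' @method tidy marker_trajectories
#' @export
tidy.marker_trajectories <- function(x, ...) {
  m <- dim(x$positions)[2]
  cols <- list(frame = seq_along(x$time), time_s = x$time)
  for (k in seq_len(m)) {
    cols[[sprintf("M%d_x", k)]] <- x$positions[, k, 1]
    cols[[sprintf("M%d_y", k)]] <- x$positions[, k, 2]
    cols[[sprintf("M%d_z", k)]] <- x$positions[, k, 3]
  }
  as_tibble(cols)
}

#' Write / read the motion-capture tabular export
#'
#' Mimics an optical-tracker CSV export: `frame`, `time_s`, then per-marker
#' X, Y, Z columns in metres, with blank cells marking occlusion.
#'
#' @param x a `marker_trajectories` object.
#' @param path file path.
#' @return `write_mocap_csv` returns `path` invisibly; `read_mocap_csv`
#'   returns a `marker_trajectories` object.
#' @export
write_mocap_csv <- function(x, path) {
  utils::write.csv(tidy(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_mocap_csv
#' @param layout marker layout to attach (the CSV itself carries none).
#' @export
read_mocap_csv <- function(path, layout = default_marker_layout()) {
  df <- utils::read.csv(path)
  m <- (ncol(df) - 2) / 3
  stopifnot(m == round(m))
  n <- nrow(df)
  positions <- array(NA_real_, c(n, m, 3))
  for (k in seq_len(m)) {
    positions[, k, 1] <- df[[sprintf("M%d_x", k)]]
    positions[, k, 2] <- df[[sprintf("M%d_y", k)]]
    positions[, k, 3] <- df[[sprintf("M%d_z", k)]]
  }
  rate <- if (n > 1) 1 / stats::median(diff(df$time_s)) else NA_real_
  new_marker_trajectories(df$time_s, positions, rate, layout)
}
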