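# Dual-axis sensor array geometry.

#' Construct a dual-axis OPM sensor array on the upper scalp
#'
#' Places `n_sensors` dual-axis magnetometers quasi-uniformly over the upper
#' hemisphere of a sphere (a Fibonacci lattice about the +Y, down-up, axis),
#' at `head_radius + standoff` from the sphere centre. Each sensor measures
#' the field along two orthogonal unit axes: one radial (along the line from
#' the sphere centre) and one tangential, giving `2 * n_sensors` channels.
#' The azimuth of the tangential axis is randomised per sensor (emulating the
#' arbitrary twist of sensors in their slots) but is deterministic given
#' `seed`.
#'
#' @param n_sensors number of dual-axis sensors (default 45, i.e. 90
#'   channels).
#' @param head_radius scalp sphere radius in metres.
#' @param standoff distance from the scalp surface to the sensitive cell
#'   centre, metres.
#' @param seed integer seed for the tangential-axis azimuths.
#' @return An object of class `opm_sensor_array` with fields `positions`
#'   (n x 3, metres, head frame), `axes` (n x 2 x 3 unit vectors: radial then
#'   tangential), `channel_names` (length 2n) and `gain_flags`.
#' @export
make_sensor_array <- function(n_sensors = 45, head_radius = 0.09,
                              standoff = 0.0065, seed = 1L) {
  if (!is.numeric(head_radius) || head_radius <= 0) {
    abort("`head_radius` must be positive.", class = "opmpipe_invalid_geometry")
  }
  if (n_sensors < 4) abort("Need at least 4 sensors.",
                           class = "opmpipe_invalid_geometry")
  r <- head_radius + standoff
  # Fibonacci lattice over polar angles [0, 100 deg] about +Y (down-up axis):
  # covers the crown down to just below the ears.
  i <- seq_len(n_sensors)
  cos_max <- cos(deg2rad(100))
  cth <- 1 - (i - 0.5) / n_sensors * (1 - cos_max)
  sth <- sqrt(pmax(0, 1 - cth^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  dirs <- cbind(sth * cos(phi), cth, sth * sin(phi)) # (x, y, z), y up
  positions <- r * dirs
  twists <- withr::with_seed(seed, runif(n_sensors, 0, 2 * pi))
  axes <- array(NA_real_, c(n_sensors, 2, 3))
  for (k in i) {
    rad <- dirs[k, ]
    ref <- if (abs(rad[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    t1 <- normalize3(cross3(ref, rad))
    t2 <- cross3(rad, t1)
    tang <- cos(twists[k]) * t1 + sin(twists[k]) * t2
    axes[k, 1, ] <- rad
    axes[k, 2, ] <- tang
  }
  channel_names <- as.vector(rbind(sprintf("S%02d-RAD", i), sprintf("S%02d-TAN", i)))
  structure(list(
    n_sensors = n_sensors,
    positions = positions,
    axes = axes,
    channel_names = channel_names,
    gain_flags = setNames(rep("ok", 2 * n_sensors), channel_names),
    head_radius = head_radius,
    standoff = standoff
  ), class = "opm_sensor_array")
}

#' Channel-level positions of a sensor array
#'
#' Channels are interleaved radial/tangential per sensor, so rows `2k-1` and
#' `2k` share the position of sensor `k`.
#'
#' @param array an `opm_sensor_array`.
#' @return 2n x 3 matrix of channel positions (metres).
#' @export
channel_positions <- function(array) {
  array$positions[rep(seq_len(array$n_sensors), each = 2), , drop = FALSE]
}

#' Channel-level sensitive axes of a sensor array
#'
#' @param array an `opm_sensor_array`.
#' @return 2n x 3 matrix of unit sensitive-axis vectors.
#' @export
channel_axes <- function(array) {
  n <- array$n_sensors
  out <- matrix(NA_real_, 2 * n, 3)
  out[seq(1, 2 * n, 2), ] <- array$axes[, 1, ]
  out[seq(2, 2 * n, 2), ] <- array$axes[, 2, ]
  out
}

#' @export
print.opm_sensor_array <- function(x, ...) {
  cat(sprintf("<opm_sensor_array> %d dual-axis sensors (%d channels), scalp radius %.3f m\n",
              x$n_sensors, 2 * x$n_sensors, x$head_radius))
  invisible(x)
}

n_channels <- function(array) 2L * array$n_sensors
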