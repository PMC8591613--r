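# Internal geometry and filtering helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix from intrinsic yaw-pitch-roll angles
#'
#' Angles are in degrees and applied intrinsically in the order yaw (about the
#' down-up Y axis), then pitch (about the right-left X axis), then roll (about
#' the back-forward Z axis): `R = Ry(yaw) Rx(pitch) Rz(roll)`. This is the
#' convention used for all rigid-body poses in the package.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_ypr <- function(yaw, pitch, roll) {
  a <- deg2rad(yaw); b <- deg2rad(pitch); c <- deg2rad(roll)
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

# Vectorised rotation entries for an angle series (degrees). Returns an
# n x 9 matrix whose rows are the rotation matrix in column-major order.
rotation_ypr_series <- function(yaw, pitch, roll) {
  a <- deg2rad(yaw); b <- deg2rad(pitch); c <- deg2rad(roll)
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  # R = Ry(a) Rx(b) Rz(c); entries worked out analytically
  cbind(
    ca * cc + sa * sb * sc,  # R11
    cb * sc,                 # R21
    -sa * cc + ca * sb * sc, # R31
    -ca * sc + sa * sb * cc, # R12
    cb * cc,                 # R22
    sa * sc + ca * sb * cc,  # R32
    sa * cb,                 # R13
    -sb,                     # R23
    ca * cb                  # R33
  )
}

# Apply an n-sample rotation series (n x 9, column-major blocks) to a single
# 3-vector; returns n x 3.
rotate_series <- function(Rser, v) {
  cbind(
    Rser[, 1] * v[1] + Rser[, 4] * v[2] + Rser[, 7] * v[3],
    Rser[, 2] * v[1] + Rser[, 5] * v[2] + Rser[, 8] * v[3],
    Rser[, 3] * v[1] + Rser[, 6] * v[2] + Rser[, 9] * v[3]
  )
}

# Euler angles (degrees, c(pitch, yaw, roll)) from a rotation matrix using the
# package convention R = Ry(yaw) Rx(pitch) Rz(roll).
euler_from_rotation <- function(R) {
  pitch <- asin(max(-1, min(1, -R[2, 3])))
  yaw <- atan2(R[1, 3], R[3, 3])
  roll <- atan2(R[2, 1], R[2, 2])
  rad2deg(c(pitch = pitch, yaw = yaw, roll = roll))
}

# Unwrap an angle series in degrees (remove 360 degree jumps).
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  corr <- cumsum(round(d / 360)) * 360
  x - c(0, corr)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

normalize3 <- function(v) v / sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth filter bidirectionally (forward and backward) so that
#' the net frequency response is the squared magnitude response and no phase
#' shift is introduced. Implemented exactly in the frequency domain: the
#' signal is extended by odd reflection at both ends (to suppress wrap-around
#' transients), multiplied by `|H(e^{i w})|^2` computed from the digital
#' Butterworth coefficients, and transformed back.
#'
#' @param x numeric vector or a samples-by-series matrix (each column is
#'   filtered independently).
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (scalar for low/high pass).
#' @param order filter order of the underlying one-pass Butterworth design.
#' @param type `"low"` or `"high"`.
#' @param pad_method `"reflect"` (odd reflection about the end points; robust
#'   for noisy signals) or `"extrapolate"` (quadratic continuation fitted to
#'   the outermost half second; far smaller edge transients for smooth,
#'   slowly varying series such as motion trajectories).
#' @return Filtered object of the same shape as `x`.
#' @export
zero_phase_filter <- function(x, rate, cutoff, order, type = c("low", "high"),
                              pad_method = c("reflect", "extrapolate")) {
  type <- match.arg(type)
  pad_method <- match.arg(pad_method)
  if (cutoff <= 0 || cutoff >= rate / 2) {
    abort("`cutoff` must lie strictly between 0 and the Nyquist frequency.")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = type)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  if (n < 4) abort("Signal too short to filter.")
  # Pad sized from the slowest pole's decay (impulse response down to ~e^-9),
  # so edge transients are negligible.
  r <- suppressWarnings(max(Mod(polyroot(rev(bf$a)))))
  pad <- if (is.finite(r) && r < 1 && r > 0) ceiling(-9 / log(r)) else 50
  pad <- max(3 * (order + 1), min(n - 1, pad))
  if (pad_method == "reflect") {
    idx_pre <- pad:1; idx_post <- n - (1:pad)
    ext <- rbind(
      2 * matrix(xm[1, ], pad, ncol(xm), byrow = TRUE) - xm[idx_pre, , drop = FALSE],
      xm,
      2 * matrix(xm[n, ], pad, ncol(xm), byrow = TRUE) - xm[idx_post, , drop = FALSE]
    )
  } else {
    fit_n <- min(n, max(8L, round(0.5 * rate)))
    extrap <- function(side) {
      idx <- if (side == "pre") seq_len(fit_n) else n - fit_n + seq_len(fit_n)
      tt <- idx - (if (side == "pre") 1 else n) # 0 at the boundary sample
      tp <- if (side == "pre") (-pad):(-1) else seq_len(pad)
      apply(xm[idx, , drop = FALSE], 2, function(v) {
        cf <- stats::lm.fit(cbind(1, tt, tt^2), v)$coefficients
        cf[1] + cf[2] * tp + cf[3] * tp^2
      })
    }
    ext <- rbind(extrap("pre"), xm, extrap("post"))
  }
  m <- nrow(ext)
  w <- 2 * pi * (0:(m - 1)) / m
  z <- exp(-1i * w)
  num <- Reduce(`+`, lapply(seq_along(bf$b), function(k) bf$b[k] * z^(k - 1)))
  den <- Reduce(`+`, lapply(seq_along(bf$a), function(k) bf$a[k] * z^(k - 1)))
  H2 <- Mod(num / den)^2
  X <- mvfft(ext)
  out <- Re(mvfft(X * H2, inverse = TRUE)) / m
  out <- out[(pad + 1):(pad + n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Squared-magnitude (bidirectional) Butterworth gain at frequency f for the
# analogue prototype; used in tests as a closed-form reference.
butter_bidir_gain <- function(f, cutoff, order) {
  1 / (1 + (f / cutoff)^(2 * order))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
}
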