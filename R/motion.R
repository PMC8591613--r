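# Motion-capture processing: occlusion gap interpolation, trajectory
# filtering, rigid-body pose solving and kinematic summaries.

# Least-squares rigid transform (Kabsch / orthogonal Procrustes, proper
# rotation enforced) mapping `from` points onto `to` points: to ~ R from + T.
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, T = ct - drop(R %*% cf),
       conditioned = sv$d[2] > 1e-9 * max(sv$d[1], .Machine$double.eps))
}

#' Interpolate occlusion gaps in marker trajectories
#'
#' Three passes, in order: (1) pattern-based fill — for every frame with at
#' least three visible markers, solve the rigid-body pose from the visible
#' subset against the template and place the occluded markers from the
#' template; (2) per-marker cubic-spline fill for remaining gaps up to
#' `max_spline_gap` samples, fitted to the data either side of the gap
#' (gaps touching the start or end of the record are never extrapolated);
#' (3) pattern-based fill again. Frames that remain unresolved are reported
#' in the `unresolved` attribute of the result.
#'
#' @param markers a `marker_trajectories` object.
#' @param template rigid marker layout (defaults to the layout carried by
#'   `markers`).
#' @param max_spline_gap longest gap (samples) the spline pass may fill;
#'   default 100 samples (0.83 s at 120 Hz).
#' @return A `marker_trajectories` object with gaps filled where possible;
#'   attribute `unresolved` is a tibble of still-missing runs.
#' @export
interpolate_gaps <- function(markers, template = NULL, max_spline_gap = 100) {
  template <- template %||% markers$layout
  P <- markers$positions
  n <- dim(P)[1]; m <- dim(P)[2]

  pattern_pass <- function(P) {
    vis <- !is.na(P[, , 1])
    fix <- which(rowSums(vis) >= 3 & rowSums(vis) < m)
    for (f in fix) {
      v <- vis[f, ]
      sol <- kabsch(template[v, , drop = FALSE],
                    matrix(P[f, v, ], sum(v), 3))
      miss <- which(!v)
      P[f, miss, ] <- sweep(template[miss, , drop = FALSE] %*% t(sol$R), 2, sol$T, `+`)
    }
    P
  }

  spline_pass <- function(P) {
    for (k in seq_len(m)) {
      ok <- !is.na(P[, k, 1])
      if (all(ok) || sum(ok) < 4) next
      r <- rle(!ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (g in which(r$values)) {
        s <- starts[g]; e <- ends[g]
        if (e - s + 1L > max_spline_gap) next
        if (s == 1L || e == n) next # no flanking data on one side
        idx_obs <- which(ok)
        for (d in 1:3) {
          sf <- splinefun(idx_obs, P[idx_obs, k, d], method = "fmm")
          P[s:e, k, d] <- sf(s:e)
        }
      }
    }
    P
  }

  P <- pattern_pass(P)
  P <- spline_pass(P)
  P <- pattern_pass(P)

  vis <- !is.na(P[, , 1])
  unresolved <- tibble(marker = integer(), start_frame = integer(),
                       end_frame = integer())
  for (k in seq_len(m)) {
    miss <- !vis[, k]
    if (any(miss)) {
      r <- rle(miss); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (g in which(r$values)) {
        unresolved <- bind_rows(unresolved,
                                tibble(marker = k, start_frame = starts[g],
                                       end_frame = ends[g]))
      }
    }
  }
  out <- new_marker_trajectories(markers$time, P, markers$rate, markers$layout)
  attr(out, "unresolved") <- unresolved
  out
}

#' Low-pass filter marker or pose trajectories (zero phase)
#'
#' Removes high-frequency jitter (e.g. marker vibration) with a Butterworth
#' low-pass applied bidirectionally, so a symmetric pulse keeps its centre
#' sample. All gaps must be interpolated first.
#'
#' @param x a `marker_trajectories` or `rigid_body_trajectory`.
#' @param cutoff low-pass cutoff, Hz (default 2).
#' @param order one-pass filter order (default 4).
#' @return Same class as `x`.
#' @export
filter_trajectory <- function(x, cutoff = 2, order = 4) {
  if (inherits(x, "marker_trajectories")) {
    if (anyNA(x$positions)) {
      abort("Marker gaps remain; run `interpolate_gaps()` first.",
            class = "opmpipe_must_interpolate_first")
    }
    n <- dim(x$positions)[1]; m <- dim(x$positions)[2]
    flat <- matrix(x$positions, n, m * 3)
    flat <- zero_phase_filter(flat, x$rate, cutoff, order, "low",
                              pad_method = "extrapolate")
    out <- new_marker_trajectories(x$time, array(flat, c(n, m, 3)), x$rate,
                                   x$layout)
    return(out)
  }
  if (inherits(x, "rigid_body_trajectory")) {
    if (anyNA(x[dof_names])) {
      abort("Pose contains missing values; interpolate first.",
            class = "opmpipe_must_interpolate_first")
    }
    rate <- attr(x, "rate")
    vals <- as.matrix(x[dof_names])
    vals <- zero_phase_filter(vals, rate, cutoff, order, "low",
                              pad_method = "extrapolate")
    return(new_rigid_body_trajectory(x$time, vals[, 1:3, drop = FALSE],
                                     vals[, 4:6, drop = FALSE], rate))
  }
  abort("`x` must be a marker_trajectories or rigid_body_trajectory.")
}

#' Solve the rigid-body pose series from marker trajectories
#'
#' Per frame, finds the least-squares rigid transform (rotation plus
#' translation, no scaling; proper rotation enforced) from the template
#' layout to the observed markers, then extracts intrinsic yaw-pitch-roll
#' Euler angles (see [rotation_ypr()]) and unwraps them over time.
#'
#' @param markers gap-free `marker_trajectories`.
#' @param template rigid layout (defaults to the layout carried by
#'   `markers`).
#' @return A `rigid_body_trajectory`; attribute `ill_conditioned` flags
#'   frames whose visible configuration was near-collinear.
#' @export
solve_rigid_body <- function(markers, template = NULL) {
  template <- template %||% markers$layout
  if (anyNA(markers$positions)) {
    abort("Markers contain gaps; run `interpolate_gaps()` first.",
          class = "opmpipe_must_interpolate_first")
  }
  n <- dim(markers$positions)[1]
  trans <- matrix(NA_real_, n, 3)
  ang <- matrix(NA_real_, n, 3) # pitch, yaw, roll
  flag <- logical(n)
  for (f in seq_len(n)) {
    sol <- kabsch(template, matrix(markers$positions[f, , ], nrow(template), 3))
    trans[f, ] <- sol$T
    ang[f, ] <- euler_from_rotation(sol$R)
    flag[f] <- !sol$conditioned
  }
  for (j in 1:3) ang[, j] <- unwrap_deg(ang[, j])
  out <- new_rigid_body_trajectory(markers$time, trans, ang, markers$rate)
  attr(out, "ill_conditioned") <- which(flag)
  out
}

#' Kinematic summaries of a pose series
#'
#' Computes the per-DOF range (max minus min), 50-bin histograms of each
#' DOF, and the per-trial maximal Euclidean displacement of the translation
#' vector relative to the trial's first sample, together with the overall
#' mean per-trial distance.
#'
#' @param pose a `rigid_body_trajectory`.
#' @param trial_windows tibble / data frame with columns `start` and `end`
#'   (seconds), one row per trial.
#' @param bins histogram bin count (default 50).
#' @return An object of class `kinematics_summary`: `dof_ranges`,
#'   `trial_distances`, `histograms`, `mean_trial_distance`.
#' @export
kinematics_summary <- function(pose, trial_windows, bins = 50) {
  vals <- as.matrix(pose[dof_names])
  dof_ranges <- tibble(
    dof = dof_names,
    unit = c(rep("m", 3), rep("deg", 3)),
    range = apply(vals, 2, function(v) diff(range(v)))
  )
  hists <- purrr::imap(setNames(as.data.frame(vals), dof_names), function(v, nm) {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    tibble(dof = nm, mid = h$mids, count = h$counts)
  }) |> bind_rows()

  tw <- as_tibble(trial_windows)
  dists <- numeric(0); keep <- logical(nrow(tw))
  for (i in seq_len(nrow(tw))) {
    idx <- which(pose$time >= tw$start[i] & pose$time <= tw$end[i])
    if (length(idx) < 2) { keep[i] <- FALSE; next }
    keep[i] <- TRUE
    ref <- vals[idx[1], 1:3]
    d <- sqrt(rowSums(sweep(vals[idx, 1:3, drop = FALSE], 2, ref)^2))
    dists <- c(dists, max(d))
  }
  if (any(!keep)) {
    inform(sprintf("%d empty trial window(s) excluded from kinematics.",
                   sum(!keep)))
  }
  trial_distances <- tibble(trial = which(keep), start = tw$start[keep],
                            end = tw$end[keep], max_distance = dists)
  structure(list(dof_ranges = dof_ranges,
                 trial_distances = trial_distances,
                 histograms = hists,
                 mean_trial_distance = mean(dists)),
            class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat("<kinematics_summary>\n")
  for (i in seq_len(nrow(x$dof_ranges))) {
    cat(sprintf("  %-6s range %8.3f %s\n", x$dof_ranges$dof[i],
                x$dof_ranges$range[i], x$dof_ranges$unit[i]))
  }
  cat(sprintf("  mean per-trial max distance: %.4f m over %d trials\n",
              x$mean_trial_distance, nrow(x$trial_distances)))
  invisible(x)
}

#' @method glance kinematics_summary
#' @export
glance.kinematics_summary <- function(x, ...) {
  out <- as.list(setNames(x$dof_ranges$range, paste0("range_", x$dof_ranges$dof)))
  out$mean_trial_distance <- x$mean_trial_distance
  out$n_trials <- nrow(x$trial_distances)
  as_tibble(out)
}

#' Synchronise a pose series with a recording's sample grid
#'
#' Linearly interpolates each degree of freedom onto the recording's sample
#' times, producing the motion regressor matrix for artefact regression.
#'
#' @param pose a `rigid_body_trajectory`.
#' @param rec an `opm_recording`.
#' @return A samples x 6 matrix with columns `x`, `y`, `z`, `pitch`, `yaw`,
#'   `roll` on the recording grid.
#' @export
synchronize <- function(pose, rec) {
  t_rec <- rec_times(rec)
  if (max(pose$time) < min(t_rec) || min(pose$time) > max(t_rec)) {
    abort("Pose and recording time ranges do not overlap.",
          class = "opmpipe_sync_error")
  }
  out <- vapply(dof_names, function(v) approx(pose$time, pose[[v]], t_rec,
                                              rule = 2)$y, numeric(length(t_rec)))
  colnames(out) <- dof_names
  out
}
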