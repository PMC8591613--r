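# Full synthetic OPM recording: moving sensors in a room field gradient,
# neural sources, line interference and white sensor noise.

#' Simulate an OPM recording from a moving participant
#'
#' Generates the sensor-space measurement for every channel `c` at time `t`:
#'
#' `y_c(t) = a_c(t) . B_room(p_c(t)) + neural_c(t) + line_c(t) + noise_c(t)`
#'
#' where `p_c(t)` and `a_c(t)` are the channel's position and sensitive axis
#' transported through the room by the head pose (the sensors move with the
#' head), `B_room` is the affine remnant-field model, and the neural term is
#' the forward projection of the dipole sources computed in the head frame
#' (and therefore motion-invariant, since the sources and sensors move
#' together). Narrowband interference lines couple to each channel through a
#' fixed spatially uniform random field direction per line. Optionally,
#' samples exceeding the magnetometer dynamic range are clipped and flagged.
#'
#' @param array an `opm_sensor_array`.
#' @param traj a `rigid_body_trajectory` (any rate; linearly interpolated to
#'   the recording grid).
#' @param room a [room_field_model()].
#' @param sources list of [dipole_source()] objects.
#' @param stim a [stimulus_train()].
#' @param noise an [noise_model()].
#' @param head_model a [head_model()] for the neural forward projection.
#' @param rate recording sample rate, Hz.
#' @param seed integer seed for noise and line phases.
#' @param clip logical: enforce the magnetometer dynamic range
#'   (`noise$clip_limit`)? Off by default; range exceedance is treated as
#'   data loss, not as a modelling target.
#' @return A list with elements `recording` (an `opm_recording`) and
#'   `ground_truth` (list: `source_series` sources x samples in A m,
#'   `artefact` channels x samples Tesla, `neural_gains` channels x sources,
#'   `events` tibble, `clipped_fraction`).
#' @export
simulate_recording <- function(array, traj, room, sources, stim, noise,
                               head_model = NULL, rate = 1000, seed = 1L,
                               clip = FALSE) {
  head_model <- head_model %||% opmpipe::head_model()
  line_freqs <- vapply(noise$line_components, `[`, numeric(1), 1)
  if (length(line_freqs) && rate < 2 * max(line_freqs)) {
    abort("`rate` must be at least twice the highest line-component frequency.")
  }
  duration <- max(traj$time)
  ns <- floor(duration * rate) + 1L
  t <- (seq_len(ns) - 1) / rate
  nch <- n_channels(array)

  # Pose interpolated onto the recording grid
  pose <- vapply(dof_names, function(v) approx(traj$time, traj[[v]], t, rule = 2)$y,
                 numeric(ns))
  Rser <- rotation_ypr_series(pose[, "yaw"], pose[, "pitch"], pose[, "roll"])
  Tr <- pose[, c("x", "y", "z")]

  pos <- channel_positions(array)
  ax <- channel_axes(array)
  Gt <- t(room$G)
  artefact <- matrix(0, nch, ns)
  for (cidx in seq_len(nch)) {
    a_room <- rotate_series(Rser, ax[cidx, ])
    p_room <- rotate_series(Rser, pos[cidx, ]) + Tr
    Bf <- sweep(p_room, 2, room$origin) %*% Gt
    Bf <- sweep(Bf, 2, room$B0, `+`)
    artefact[cidx, ] <- rowSums(a_room * Bf)
  }

  # Neural term: forward-projected dipole sources, head frame
  events <- tibble(label = "tone",
                   sample = as.integer(round(stim$onsets * rate)) + 1L)
  events <- events[events$sample >= 1 & events$sample <= ns, ]
  nsrc <- length(sources)
  source_series <- matrix(0, max(1, nsrc), ns)
  gains <- matrix(0, nch, max(1, nsrc))
  neural <- matrix(0, nch, ns)
  if (nsrc > 0) {
    for (k in seq_len(nsrc)) {
      src <- sources[[k]]
      L <- lead_field(head_model, array, src$position)
      gains[, k] <- drop(L %*% src$orientation)
      s <- numeric(ns)
      if (src$trial_locked) {
        for (on in stim$onsets) {
          i0 <- max(1L, floor(on * rate) + 1L)
          i1 <- min(ns, floor((on + 0.6) * rate) + 1L)
          if (i1 >= i0) s[i0:i1] <- s[i0:i1] + src$waveform(t[i0:i1] - on)
        }
      } else {
        s <- src$waveform(t)
      }
      source_series[k, ] <- s
      neural <- neural + outer(gains[, k], s)
    }
  }

  data <- withr::with_seed(seed, {
    d <- artefact + neural
    for (lc in noise$line_components) {
      phase <- runif(1, 0, 2 * pi)
      dir <- normalize3(rnorm(3))
      coupling <- drop(ax %*% dir)
      d <- d + outer(coupling * lc[2], sin(2 * pi * lc[1] * t + phase))
    }
    if (noise$white_density > 0) {
      d <- d + matrix(rnorm(nch * ns, sd = noise$white_density * sqrt(rate / 2)),
                      nch, ns)
    }
    d
  })

  clipped_fraction <- 0
  gain_flags <- setNames(rep("ok", nch), array$channel_names)
  if (clip) {
    lim <- noise$clip_limit
    over <- abs(data) > lim
    clipped_fraction <- mean(over)
    if (clipped_fraction > 0.5) {
      warn(sprintf("%.0f%% of samples exceed the dynamic range.",
                   100 * clipped_fraction))
    }
    data[over] <- sign(data[over]) * lim
    gain_flags[rowSums(over) > 0] <- "clipped"
  }
  array$gain_flags <- gain_flags

  rec <- new_recording(data, rate, array, events)
  rec <- record_stage(rec, "simulate", seed = seed, rate = rate, clip = clip)
  list(recording = rec,
       ground_truth = list(source_series = source_series,
                           artefact = artefact,
                           neural_gains = gains,
                           events = events,
                           clipped_fraction = clipped_fraction))
}
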