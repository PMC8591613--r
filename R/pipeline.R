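# End-to-end orchestration: presets for the three recording conditions,
# per-condition pipeline runs, cross-condition comparison, the
# motion-regression / HFC ablation grid and the regularisation sweep.

#' Default bilateral auditory sources
#'
#' A pair of mirror-symmetric current dipoles in the supratemporal plane
#' (head frame: x right-left, y down-up, z back-forward), with tangential
#' orientations (mirror images of each other) and the canonical evoked
#' waveform, fully correlated across hemispheres as in auditory stimulation.
#'
#' @param position right-hemisphere dipole position (the left is its
#'   mirror), metres.
#' @param scale moment scale factor passed to [evoked_components()].
#' @return List of two [dipole_source()] objects.
#' @export
auditory_sources <- function(position = c(0.048, 0.012, 0.005), scale = 1) {
  orient_r <- normalize3(c(0, 0.8, 0.6) - sum(c(0, 0.8, 0.6) *
                                                normalize3(position)) * normalize3(position))
  pos_l <- position * c(-1, 1, 1)
  orient_l <- orient_r * c(-1, 1, 1)
  wf <- function(t) evoked_waveform(t, evoked_components(scale))
  list(
    dipole_source(position, orient_r, wf),
    dipole_source(pos_l, orient_l, wf)
  )
}

#' Build the configuration for one recording condition
#'
#' Named presets reproduce the three study conditions: `sitting` (head at
#' the room centre, negligible movement), `standing_still` (head displaced
#' from the room centre into a steeper part of the field gradient, residual
#' sway only) and `standing_moving` (same location plus large continuous
#' head movement). Motion regression defaults to off for the still presets
#' and on for the moving one, because regressing tracking data into still
#' recordings injects tracking noise.
#'
#' @param preset `"sitting"`, `"standing_still"` or `"standing_moving"`.
#' @param duration recording length, seconds (default 60; `full_length =
#'   TRUE` restores ~285 s and ~570 tones).
#' @param rate sample rate, Hz.
#' @param seed base integer seed; motion, noise and trial-selection seeds
#'   are derived from it.
#' @param full_length use the full-study recording length.
#' @param grid_resolution source-grid spacing, metres.
#' @param lambda_percent beamformer regularisation.
#' @param motion_regression,hfc stage switches; `NULL` uses the preset
#'   default.
#' @param n_equalize trial count for cross-condition equalisation; `NULL`
#'   picks the largest count available in every condition.
#' @return A `run_config` list.
#' @export
preset_config <- function(preset = c("sitting", "standing_still", "standing_moving"),
                          duration = 60, rate = 1000, seed = 1L,
                          full_length = FALSE, grid_resolution = 0.005,
                          lambda_percent = 0.1,
                          motion_regression = NULL, hfc = NULL,
                          n_equalize = NULL) {
  preset <- match.arg(preset)
  if (full_length) duration <- 285
  moving <- preset == "standing_moving"
  standing <- preset != "sitting"
  # per-preset seed offsets: the three conditions are independent recordings
  # (independent noise and motion realisations) sharing only the neural
  # ground truth and the sensor array
  poff <- 101L * match(preset, c("sitting", "standing_still", "standing_moving"))
  cfg <- list(
    preset = preset,
    duration = duration,
    rate = rate,
    seeds = list(array = 11L, motion = seed * 13L + 1L + poff,
                 noise = seed * 17L + 2L + poff,
                 markers = seed * 19L + 3L + poff,
                 trials = seed * 23L + 4L + poff),
    # head start position in the room: standing presets are displaced from
    # the room centre into a higher-field region of the gradient
    head_offset = if (standing) c(0, 0.4, 0) else c(0, 0, 0),
    gradient_scale = 1,
    translation_range = if (moving) c(1.0, 0.5, 1.15) else
      if (standing) c(0.004, 0.003, 0.004) else c(0.002, 0.0015, 0.002),
    rotation_range = if (moving) c(110, 150, 180) else
      if (standing) c(1, 1, 1) else c(0.5, 0.5, 0.5),
    # wandering, naturalistic motion: slow enough that a ~1 m range coexists
    # with ~5 cm of movement per 0.5 s trial; still presets sway gently
    smoothness_cutoff = if (moving) 0.04 else 0.3,
    occlusion = if (moving) c(0.089, 0.029, 1.24) else c(0.0086, 0.026, 1.2),
    motion_regression = motion_regression %||% moving,
    hfc = hfc %||% TRUE,
    spectral_targets = c(seq(50, 450, by = 50), 120, 83),
    highpass = c(cutoff = 2, order = 5),
    lowpass = c(cutoff = 40, order = 6),
    artefact = list(chunk_s = 5, range_thresh = 100e-12),
    epoch = list(tmin = -0.2, tmax = 0.5, baseline = c(-0.1, 0)),
    grid_resolution = grid_resolution,
    lambda_percent = lambda_percent,
    roi_radius = 0.012,
    n_equalize = n_equalize,
    source_scale = 1
  )
  class(cfg) <- "run_config"
  cfg
}

# Per-trial maximal field change: per trial window, the largest across
# channels of (max - min) within the window; averaged over trials.
mean_trial_field_change <- function(rec, onsets_s, trial_s = 0.5) {
  ns <- ncol(rec$data)
  changes <- vapply(onsets_s, function(on) {
    i0 <- floor(on * rec$rate) + 1L
    i1 <- min(ns, i0 + round(trial_s * rec$rate) - 1L)
    if (i1 <= i0) return(NA_real_)
    seg <- rec$data[, i0:i1, drop = FALSE]
    max(apply(seg, 1, function(v) diff(range(v))))
  }, numeric(1))
  mean(changes, na.rm = TRUE)
}

#' Run one condition end to end
#'
#' Simulates the condition (sensor array, head motion, markers, recording),
#' processes the motion capture into a pose series, runs the sensor-space
#' interference-suppression cascade, and beamforms. Returns a results bundle
#' with kinematics, the stage-wise field-change table, the sensor-level
#' evoked response, the NAI source map, the ROI virtual channel and PSD
#' diagnostics, plus ground truth and a manifest of seeds and parameters.
#'
#' @param cfg a `run_config` from [preset_config()].
#' @param forward optional precomputed forward bundle (list with `head`,
#'   `grid`, `lf`, `array`) to share across conditions.
#' @param keep_epochs keep the epoched data in the bundle (needed for
#'   regularisation sweeps).
#' @return An `opm_condition_result` list.
#' @export
run_condition <- function(cfg, forward = NULL, keep_epochs = TRUE) {
  array <- forward$array %||% make_sensor_array(seed = cfg$seeds$array)
  head <- forward$head %||% head_model()
  room <- room_field_model()
  room$G <- room$G * cfg$gradient_scale
  n_tones <- floor((cfg$duration - 1.6) / 0.5)
  stim <- stimulus_train(n_tones = n_tones, isi = 0.5, t_start = 1.0)
  sources <- auditory_sources(scale = cfg$source_scale)

  traj <- simulate_motion(cfg$duration, rate = 120,
                          translation_range = cfg$translation_range,
                          rotation_range = cfg$rotation_range,
                          smoothness_cutoff = cfg$smoothness_cutoff,
                          seed = cfg$seeds$motion)
  # place the head at its in-room start position
  traj$x <- traj$x + cfg$head_offset[1]
  traj$y <- traj$y + cfg$head_offset[2]
  traj$z <- traj$z + cfg$head_offset[3]

  markers <- simulate_markers(traj, occlusion = cfg$occlusion,
                              seed = cfg$seeds$markers)
  markers <- interpolate_gaps(markers)
  # any unresolved gaps (edge-touching, rare) are bridged linearly so the
  # pose series stays defined for regression
  markers_f <- filter_trajectory(fill_residual_gaps(markers), cutoff = 2, order = 4)
  pose <- solve_rigid_body(markers_f)

  sim <- simulate_recording(array, traj, room, sources, stim,
                            noise_model(), head, rate = cfg$rate,
                            seed = cfg$seeds$noise)
  rec <- sim$recording
  raw_data <- rec$data # kept for the raw-PSD diagnostic
  gt <- sim$ground_truth
  onsets_s <- (gt$events$sample - 1) / cfg$rate

  trial_windows <- tibble(start = onsets_s, end = onsets_s + 0.5)
  kin <- kinematics_summary(pose, trial_windows)

  stage_table <- tibble(stage = "raw",
                        field_change = mean_trial_field_change(rec, onsets_s))
  regressors <- synchronize(pose, rec)
  if (cfg$motion_regression) {
    rec <- regress_motion(rec, regressors)
    stage_table <- bind_rows(stage_table, tibble(
      stage = "motion_regression",
      field_change = mean_trial_field_change(rec, onsets_s)))
  }
  if (cfg$hfc) {
    rec <- homogeneous_field_correction(rec)
    stage_table <- bind_rows(stage_table, tibble(
      stage = "hfc", field_change = mean_trial_field_change(rec, onsets_s)))
  }
  rec <- spectral_interpolation(rec, targets = cfg$spectral_targets)
  rec <- filter_zero_phase(rec, "highpass", cfg$highpass["cutoff"],
                           cfg$highpass["order"])
  stage_table <- bind_rows(stage_table, tibble(
    stage = "highpass", field_change = mean_trial_field_change(rec, onsets_s)))
  rec <- detect_artefact_segments(rec, chunk_s = cfg$artefact$chunk_s,
                                  range_thresh = cfg$artefact$range_thresh)
  rec <- filter_zero_phase(rec, "lowpass", cfg$lowpass["cutoff"],
                           cfg$lowpass["order"])
  epochs <- epoch_and_baseline(rec, tmin = cfg$epoch$tmin, tmax = cfg$epoch$tmax,
                               baseline = cfg$epoch$baseline)
  evoked <- evoked_average(epochs)

  # forward model shared across conditions
  if (is.null(forward)) {
    grid <- make_grid(head, resolution = cfg$grid_resolution)
    lf <- lead_field_grid(head, array, grid)
    forward <- list(head = head, grid = grid, lf = lf, array = array)
  }
  grid <- forward$grid; lf <- forward$lf

  map <- nai_map(epochs, grid, lf, lambda_percent = cfg$lambda_percent)
  src_pos <- do.call(rbind, lapply(sources, `[[`, "position"))
  roi <- roi_points(grid, src_pos, cfg$roi_radius)
  vc <- roi_virtual_channel(epochs, grid, lf, roi,
                            lambda_percent = cfg$lambda_percent)

  # PSD diagnostics on the channel with the strongest M100 deflection
  m100_mask <- evoked$times >= 0.08 & evoked$times < 0.12
  best_ch <- which.max(apply(abs(evoked$data[, m100_mask, drop = FALSE]), 1, max))
  source_series <- apply_spatial_filter(rec, vc$weights)
  psds <- list(
    raw_sensor = welch_psd(raw_data[best_ch, ], rec$rate, band = c(0, 45)),
    preprocessed_sensor = welch_psd(rec$data[best_ch, ], rec$rate, band = c(0, 45)),
    source = welch_psd(source_series, rec$rate, band = c(0, 45))
  )

  structure(list(
    preset = cfg$preset,
    config = cfg,
    kinematics = kin,
    stage_table = stage_table,
    evoked = evoked,
    best_channel = best_ch,
    nai = map,
    virtual_channel = vc,
    psds = psds,
    epochs = if (keep_epochs) epochs else NULL,
    recording_history = rec$history,
    bad_segments = rec$bad_segments,
    ground_truth = list(source_series = gt$source_series,
                        events = gt$events,
                        sources = sources,
                        onsets_s = onsets_s),
    forward = forward,
    manifest = list(package_version = as.character(utils::packageVersion("opmpipe")),
                    preset = cfg$preset, seeds = cfg$seeds,
                    duration = cfg$duration, rate = cfg$rate,
                    motion_regression = cfg$motion_regression, hfc = cfg$hfc,
                    lambda_percent = cfg$lambda_percent,
                    grid_resolution = cfg$grid_resolution,
                    n_trials_kept = n_trials(epochs))
  ), class = "opm_condition_result")
}

# Grid points within `radius` of any source position; falls back to the
# nearest grid point per source when the lattice is coarser than the radius.
roi_points <- function(grid, src_pos, radius) {
  d <- apply(grid$points, 1, function(p) min(row_norms(sweep(src_pos, 2, p))))
  roi <- which(d < radius)
  if (!length(roi)) {
    roi <- unique(vapply(seq_len(nrow(src_pos)), function(k) {
      which.min(row_norms(sweep(grid$points, 2, src_pos[k, ])))
    }, integer(1)))
  }
  roi
}

# replace any still-missing marker samples by per-marker linear
# interpolation so the pose series stays defined (rare; edge gaps only)
fill_residual_gaps <- function(markers) {
  P <- markers$positions
  n <- dim(P)[1]
  for (k in seq_len(dim(P)[2])) {
    for (d in 1:3) {
      v <- P[, k, d]
      if (anyNA(v)) {
        ok <- which(!is.na(v))
        P[, k, d] <- approx(ok, v[ok], seq_len(n), rule = 2)$y
      }
    }
  }
  new_marker_trajectories(markers$time, P, markers$rate, markers$layout)
}

#' @export
print.opm_condition_result <- function(x, ...) {
  cat(sprintf("<opm_condition_result> preset '%s', %d trials kept\n",
              x$preset, x$manifest$n_trials_kept))
  print(x$stage_table)
  invisible(x)
}

#' @method glance opm_condition_result
#' @export
glance.opm_condition_result <- function(x, ...) {
  pk <- x$virtual_channel$times[which.max(abs(x$virtual_channel$average))]
  tibble(
    preset = x$preset,
    n_trials = x$manifest$n_trials_kept,
    mean_trial_distance = x$kinematics$mean_trial_distance,
    raw_field_change = x$stage_table$field_change[x$stage_table$stage == "raw"],
    final_field_change = tail(x$stage_table$field_change, 1),
    peak_latency = pk
  )
}

#' Run the three-condition study
#'
#' Runs each preset end to end with a shared sensor array, forward model and
#' neural ground truth, equalises trial counts, and reports the
#' cross-condition correlation matrix of the ROI evoked waveforms over the
#' 0-0.3 s window.
#'
#' @param presets character vector of presets to run.
#' @param seed base seed.
#' @param duration seconds per condition.
#' @param ... further arguments passed to [preset_config()].
#' @return An `opm_study_result`: named list of condition bundles plus
#'   `roi_correlations` and `comparison` tibbles.
#' @export
run_study <- function(presets = c("sitting", "standing_still", "standing_moving"),
                      seed = 1L, duration = 60, ...) {
  cfgs <- purrr::map(presets, function(p)
    preset_config(p, duration = duration, seed = seed, ...))
  names(cfgs) <- presets
  forward <- NULL
  results <- list()
  for (p in presets) {
    res <- run_condition(cfgs[[p]], forward = forward)
    forward <- res$forward
    results[[p]] <- res
  }
  # equalise trial counts across conditions, then rebuild each ROI virtual
  # channel from the equalised trials so the comparison has matched power
  counts <- vapply(results, function(r) n_trials(r$epochs), integer(1))
  n_eq <- cfgs[[1]]$n_equalize %||% min(counts)
  ep_eq <- equalize_trials(purrr::map(results, "epochs"), n = n_eq,
                           seed = seed + 1000L)
  grid <- forward$grid; lf <- forward$lf
  for (p in presets) {
    src_pos <- do.call(rbind, lapply(results[[p]]$ground_truth$sources,
                                     `[[`, "position"))
    roi <- roi_points(grid, src_pos, cfgs[[p]]$roi_radius)
    results[[p]]$virtual_channel <- roi_virtual_channel(
      ep_eq[[p]], grid, lf, roi, lambda_percent = cfgs[[p]]$lambda_percent)
    results[[p]]$manifest$n_trials_equalized <- n_eq
  }
  roi_correlations <- roi_correlation_matrix(
    purrr::map(results, "virtual_channel"), window = c(0, 0.3))
  comparison <- purrr::map(results, glance) |> bind_rows()
  structure(list(conditions = results, roi_correlations = roi_correlations,
                 comparison = comparison, seed = seed, n_equalized = n_eq),
            class = "opm_study_result")
}

#' Pairwise correlation of ROI evoked waveforms
#'
#' @param vcs named list of `opm_virtual_channel` objects.
#' @param window correlation window, seconds.
#' @return Correlation matrix.
#' @export
roi_correlation_matrix <- function(vcs, window = c(0, 0.3)) {
  series <- purrr::map(vcs, function(v) {
    m <- v$times >= window[1] & v$times < window[2]
    v$average[m]
  })
  n <- length(series)
  out <- matrix(1, n, n, dimnames = list(names(vcs), names(vcs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- stats::cor(series[[i]], series[[j]])
  }
  out
}

#' Motion-regression / HFC ablation grid
#'
#' Re-runs the moving-condition pipeline under the four combinations of
#' motion regression and homogeneous field correction, all other stages
#' identical, and reports the pairwise ROI-waveform correlations and
#' sensor/source PSDs per combination.
#'
#' @param seed base seed.
#' @param duration seconds.
#' @param ... passed to [preset_config()].
#' @return An `opm_ablation_result` with `results` (named list),
#'   `roi_correlations`, and `summary` tibble.
#' @export
ablation_grid <- function(seed = 1L, duration = 60, ...) {
  combos <- expand.grid(motion_regression = c(FALSE, TRUE),
                        hfc = c(FALSE, TRUE))
  labels <- sprintf("mr=%s_hfc=%s",
                    ifelse(combos$motion_regression, "on", "off"),
                    ifelse(combos$hfc, "on", "off"))
  forward <- NULL
  results <- list()
  for (i in seq_len(nrow(combos))) {
    cfg <- preset_config("standing_moving", duration = duration, seed = seed,
                         motion_regression = combos$motion_regression[i],
                         hfc = combos$hfc[i], ...)
    res <- run_condition(cfg, forward = forward)
    forward <- res$forward
    results[[labels[i]]] <- res
  }
  roi_correlations <- roi_correlation_matrix(
    purrr::map(results, "virtual_channel"), window = c(0, 0.3))
  summary <- purrr::map(results, glance) |> bind_rows() |>
    mutate(combo = labels, .before = 1)
  structure(list(results = results, roi_correlations = roi_correlations,
                 summary = summary), class = "opm_ablation_result")
}

#' Regularisation sweep
#'
#' Recomputes the NAI map and the ROI series for a ladder of regularisation
#' values on an existing condition bundle, reporting map focality and the
#' low-frequency (2-6 Hz) power of the single-trial ROI series. Increasing
#' regularisation makes the beamformer less spatially specific, degrading
#' both.
#'
#' @param result an `opm_condition_result` run with `keep_epochs = TRUE`.
#' @param lambdas regularisation values in percent (default 0, 1, 10, 100,
#'   1000).
#' @return A tibble: `lambda_percent`, `focality`, `roi_lowfreq_db`.
#' @export
lambda_sweep <- function(result, lambdas = c(0, 1, 10, 100, 1000)) {
  if (is.null(result$epochs)) abort("Condition bundle was run without epochs.")
  epochs <- result$epochs
  grid <- result$forward$grid
  lf <- result$forward$lf
  src_pos <- do.call(rbind, lapply(result$ground_truth$sources, `[[`, "position"))
  roi <- roi_points(grid, src_pos, result$config$roi_radius)
  rows <- purrr::map(lambdas, function(lam) {
    map <- nai_map(epochs, grid, lf, lambda_percent = lam)
    vc <- roi_virtual_channel(epochs, grid, lf, roi, lambda_percent = lam)
    # low-frequency power of the concatenated single-trial series
    series <- as.vector(t(vc$trials))
    psd <- welch_psd(series, epochs$rate, seg_s = 0.7, band = c(2, 6))
    tibble(lambda_percent = lam, focality = map_focality(map),
           roi_lowfreq_db = 10 * log10(mean(psd$power)))
  })
  bind_rows(rows)
}
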