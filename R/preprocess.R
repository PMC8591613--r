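# Sensor-space interference suppression cascade: downsampling, windowed
# motion regression, homogeneous field correction, spectral interpolation,
# zero-phase filtering, automated artefact-segment rejection, epoching.

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase Butterworth, order 8, cutoff at 40% of
#' the target rate) followed by decimation. The original rate must be an
#' integer multiple of the target. Events are remapped to the nearest new
#' sample.
#'
#' @param rec an `opm_recording`.
#' @param target target rate, Hz (default 1000).
#' @return Downsampled `opm_recording`.
#' @export
downsample <- function(rec, target = 1000) {
  if (target > rec$rate) {
    abort("Upsampling is not supported.", class = "opmpipe_upsampling")
  }
  if (target == rec$rate) return(record_stage(rec, "downsample", target = target))
  factor <- rec$rate / target
  if (abs(factor - round(factor)) > 1e-9) {
    abort("`rate` must be an integer multiple of `target`.")
  }
  factor <- as.integer(round(factor))
  filt <- t(zero_phase_filter(t(rec$data), rec$rate, 0.4 * target, 8, "low"))
  keep <- seq(1, ncol(rec$data), by = factor)
  rec$data <- filt[, keep, drop = FALSE]
  rec$rate <- target
  rec$events$sample <- as.integer(round((rec$events$sample - 1) / factor) + 1)
  record_stage(rec, "downsample", target = target)
}

#' Windowed multiple linear regression of motion artefacts
#'
#' Regresses each channel on the six rigid-body degrees of freedom
#' (plus an intercept) in overlapping windows, subtracting the fitted part.
#' Windows are recombined with a cosine-squared cross-fade so the output is
#' continuous. Windows in which the motion regressors are (near) constant —
#' e.g. still recordings — are fitted with the intercept only and flagged,
#' preventing tracking noise from being injected into still data.
#'
#' @param rec an `opm_recording`.
#' @param regressors samples x 6 matrix from [synchronize()].
#' @param window_s window length, seconds (default 10).
#' @param overlap_frac fractional overlap between consecutive windows
#'   (default 0.5).
#' @return Residual `opm_recording`; attribute `windows` is a tibble with
#'   per-window start, mean R-squared and a `motion_used` flag.
#' @export
regress_motion <- function(rec, regressors, window_s = 10, overlap_frac = 0.5) {
  ns <- ncol(rec$data)
  if (nrow(regressors) != ns) {
    abort("`regressors` must be aligned to the recording sample grid.")
  }
  win <- min(ns, round(window_s * rec$rate))
  step <- max(1L, round(win * (1 - overlap_frac)))
  starts <- seq(1L, max(1L, ns - win + 1L), by = step)
  if (tail(starts, 1) + win - 1L < ns) starts <- c(starts, ns - win + 1L)

  Yt <- t(rec$data) # samples x channels
  acc <- matrix(0, ns, ncol(Yt))
  wacc <- numeric(ns)
  ramp <- round(win * overlap_frac)
  info <- tibble(window = seq_along(starts), start_s = (starts - 1) / rec$rate,
                 r2_mean = NA_real_, motion_used = NA)
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + win - 1L)
    Xw <- regressors[idx, , drop = FALSE]
    usable <- apply(Xw, 2, function(v) sd(v) > 1e-12)
    Yw <- Yt[idx, , drop = FALSE]
    if (any(usable)) {
      X <- cbind(1, Xw[, usable, drop = FALSE])
      if (qr(X)$rank < ncol(X)) usable[] <- FALSE
    }
    if (any(usable)) {
      X <- cbind(1, Xw[, usable, drop = FALSE])
      fit <- stats::lm.fit(X, Yw)
      resid <- fit$residuals
      ssr <- colSums(resid^2)
      sst <- colSums(sweep(Yw, 2, colMeans(Yw))^2)
      info$r2_mean[wi] <- mean(1 - ssr / pmax(sst, .Machine$double.xmin))
      info$motion_used[wi] <- TRUE
    } else {
      resid <- sweep(Yw, 2, colMeans(Yw))
      info$r2_mean[wi] <- 0
      info$motion_used[wi] <- FALSE
    }
    # cosine-squared cross-fade weights; flat at the record boundaries
    w <- rep(1, win)
    if (ramp > 0) {
      up <- sin(pi / 2 * seq_len(ramp) / (ramp + 1))^2
      if (wi > 1) w[seq_len(ramp)] <- up
      if (wi < length(starts)) w[win - ramp + seq_len(ramp)] <- rev(up)
    }
    acc[idx, ] <- acc[idx, ] + resid * w
    wacc[idx] <- wacc[idx] + w
  }
  rec$data <- t(acc / wacc)
  rec <- record_stage(rec, "regress_motion", window_s = window_s,
                      overlap_frac = overlap_frac)
  attr(rec, "windows") <- info
  rec
}

#' Homogeneous field correction
#'
#' Approximates magnetic interference as a spatially constant field and
#' removes it sample by sample: with `A` the channels x 3 matrix of unit
#' sensitive-axis orientations, the uniform field estimate at each sample is
#' `u = pinv(A) y`, and `A u` is subtracted. Uses orientation information
#' only, not sensor positions. Neural (dipolar) topographies project weakly
#' onto the three-dimensional uniform basis of a whole-head dual-axis array,
#' so the neural signal is largely retained.
#'
#' @param rec an `opm_recording`.
#' @return The cleaned `opm_recording`; the removed per-sample uniform field
#'   (3 x samples, Tesla) is stored as attribute `hfc_field`.
#' @export
homogeneous_field_correction <- function(rec) {
  A <- channel_axes(rec$array)
  if (qr(A)$rank < 3) {
    abort("Channel axes do not span 3 dimensions; cannot estimate a uniform field.",
          class = "opmpipe_hfc_rank")
  }
  AtA <- crossprod(A)
  U <- solve(AtA, t(A) %*% rec$data) # 3 x samples
  rec$data <- rec$data - A %*% U
  rec <- record_stage(rec, "hfc")
  attr(rec, "hfc_field") <- U
  rec
}

#' Spectral interpolation of narrowband interference
#'
#' Removes high-amplitude spectral peaks (mains harmonics, camera-system
#' lines) without the ringing of notch filters: per channel, the amplitudes
#' of frequency-domain bins within `halfwidth` of each target are replaced
#' by the mean amplitude of the flanking bands (`halfwidth` to `halfwidth +
#' neighbour` away), keeping the phases. Real-valuedness and length are
#' preserved.
#'
#' @param rec an `opm_recording`.
#' @param targets frequencies to interpolate, Hz. Targets at or above the
#'   Nyquist frequency are dropped with a message. Default: 50 Hz and
#'   harmonics up to 500 Hz, plus 120 Hz and 83 Hz.
#' @param halfwidth half-width of the replaced band, Hz.
#' @param neighbour width of the flanking bands used as the amplitude
#'   reference, Hz.
#' @return Cleaned `opm_recording`.
#' @export
spectral_interpolation <- function(rec, targets = c(seq(50, 500, by = 50), 120, 83),
                                   halfwidth = 0.5, neighbour = 1.0) {
  nyq <- rec$rate / 2
  drop_t <- targets >= nyq
  if (any(drop_t)) {
    inform(sprintf("Dropping %d spectral-interpolation target(s) at/above Nyquist.",
                   sum(drop_t)))
    targets <- targets[!drop_t]
  }
  targets <- sort(unique(targets))
  if (length(targets) > 1 &&
      any(diff(targets) < 2 * (halfwidth + neighbour))) {
    inform("Some spectral-interpolation bands overlap; they are processed in sequence.")
  }
  ns <- ncol(rec$data)
  X <- mvfft(t(rec$data)) # samples x channels, bins in columns? rows = freq bins
  freqs <- (seq_len(ns) - 1) * rec$rate / ns
  f_fold <- pmin(freqs, rec$rate - freqs)
  for (tg in targets) {
    bin_idx <- which(abs(f_fold - tg) <= halfwidth)
    flank_idx <- which(abs(f_fold - tg) > halfwidth &
                         abs(f_fold - tg) <= halfwidth + neighbour)
    if (!length(bin_idx) || !length(flank_idx)) next
    ref_amp <- colMeans(abs(X[flank_idx, , drop = FALSE]))
    amp <- abs(X[bin_idx, , drop = FALSE])
    scale <- sweep(1 / pmax(amp, .Machine$double.xmin), 2, ref_amp, `*`)
    X[bin_idx, ] <- X[bin_idx, , drop = FALSE] * scale
  }
  rec$data <- t(Re(mvfft(X, inverse = TRUE)) / ns)
  record_stage(rec, "spectral_interpolation", targets = targets,
               halfwidth = halfwidth, neighbour = neighbour)
}

#' Zero-phase Butterworth filtering of a recording
#'
#' Bidirectional (zero phase) high- or low-pass filter. The canonical
#' pipeline applies a 2 Hz order-5 high-pass before artefact detection and a
#' 40 Hz order-6 low-pass after it.
#'
#' @param rec an `opm_recording`.
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff Hz.
#' @param order one-pass filter order.
#' @return Filtered `opm_recording`.
#' @export
filter_zero_phase <- function(rec, kind = c("highpass", "lowpass"), cutoff,
                              order) {
  kind <- match.arg(kind)
  type <- if (kind == "highpass") "high" else "low"
  rec$data <- t(zero_phase_filter(t(rec$data), rec$rate, cutoff, order, type))
  record_stage(rec, paste0("filter_", kind), cutoff = cutoff, order = order)
}

#' Automated artefact-segment detection
#'
#' Screens the recording in consecutive chunks and flags a chunk when
#' (i) any channel's field change (max minus min within the chunk) exceeds
#' `range_thresh`; (ii) any channel's high-frequency-band envelope is an
#' outlier (z-score vs the channel's across-chunk median) — intermittent
#' high-frequency noise such as cable rubbing; or (iii) the chunk's
#' cross-channel median absolute first difference is an outlier — high
#' amplitude steps present across all channels. Flags are appended to
#' `rec$bad_segments` with reason codes `range` / `hf_noise` / `step`.
#'
#' @param rec an `opm_recording` (apply after high-pass, before low-pass).
#' @param chunk_s chunk length, seconds.
#' @param range_thresh field-change threshold, Tesla (default 100 pT per
#'   chunk).
#' @param hf_band frequency band for criterion (ii); `NULL` uses 100 Hz to
#'   Nyquist, and the criterion is skipped when the band is empty.
#' @param hf_z,step_z z-score thresholds for criteria (ii) and (iii).
#' @return `opm_recording` with updated `bad_segments`.
#' @export
detect_artefact_segments <- function(rec, chunk_s = 5, range_thresh = 100e-12,
                                     hf_band = NULL, hf_z = 5, step_z = 5) {
  ns <- ncol(rec$data)
  chunk <- max(2L, round(chunk_s * rec$rate))
  starts <- seq(1L, ns, by = chunk)
  nck <- length(starts)
  reasons <- vector("list", nck)

  # (i) range exceedance
  # (iii) cross-channel median absolute step
  step_stat <- numeric(nck)
  range_flag <- logical(nck)
  d_abs <- abs(rec$data[, -1, drop = FALSE] - rec$data[, -ns, drop = FALSE])
  med_step <- apply(d_abs, 2, median)
  for (ci in seq_len(nck)) {
    idx <- starts[ci]:min(ns, starts[ci] + chunk - 1L)
    seg <- rec$data[, idx, drop = FALSE]
    rng <- apply(seg, 1, function(v) diff(range(v)))
    range_flag[ci] <- any(rng > range_thresh)
    step_stat[ci] <- max(med_step[pmin(idx[-length(idx)], ns - 1L)])
  }
  # MAD floored at 5% of the median so that near-identical chunks (or mild
  # filter-edge transients) cannot produce huge z-scores
  s_med <- median(step_stat)
  s_mad <- max(mad(step_stat), 0.05 * s_med)
  step_flag <- if (s_mad > 0) (step_stat - s_med) / s_mad > step_z else rep(FALSE, nck)

  # (ii) high-frequency envelope outliers
  hf_flag <- rep(FALSE, nck)
  lo <- if (is.null(hf_band)) 100 else hf_band[1]
  if (lo < rec$rate / 2 * 0.95) {
    hf <- t(zero_phase_filter(t(rec$data), rec$rate, lo, 4, "high"))
    env <- matrix(NA_real_, nrow(rec$data), nck)
    for (ci in seq_len(nck)) {
      idx <- starts[ci]:min(ns, starts[ci] + chunk - 1L)
      env[, ci] <- rowMeans(abs(hf[, idx, drop = FALSE]))
    }
    e_med <- apply(env, 1, median)
    e_mad <- pmax(apply(env, 1, mad), 0.05 * e_med)
    z <- (env - e_med) / ifelse(e_mad > 0, e_mad, Inf)
    hf_flag <- apply(z, 2, max) > hf_z
  }

  new_bad <- tibble(start_s = numeric(), end_s = numeric(), reason = character())
  for (ci in seq_len(nck)) {
    rs <- c(if (range_flag[ci]) "range", if (hf_flag[ci]) "hf_noise",
            if (step_flag[ci]) "step")
    if (length(rs)) {
      new_bad <- bind_rows(new_bad, tibble(
        start_s = (starts[ci] - 1) / rec$rate,
        end_s = min(ns, starts[ci] + chunk - 1L) / rec$rate,
        reason = paste(rs, collapse = "+")
      ))
    }
  }
  rec$bad_segments <- bind_rows(rec$bad_segments, new_bad)
  record_stage(rec, "detect_artefacts", chunk_s = chunk_s,
               range_thresh = range_thresh, n_flagged = nrow(new_bad))
}

#' Epoch a recording around stimulus events and baseline-correct
#'
#' Cuts trials in the half-open window `[onset + tmin, onset + tmax)` and
#' subtracts, per trial and channel, the mean over the baseline window.
#' Trials that extend beyond the record or overlap any bad segment are
#' dropped with a reason.
#'
#' @param rec an `opm_recording`.
#' @param events tibble with a `sample` column; defaults to `rec$events`.
#' @param tmin,tmax epoch window relative to onset, seconds (defaults -0.2
#'   and 0.5, i.e. 0.7 s trials).
#' @param baseline baseline window, seconds (default `c(-0.1, 0)`).
#' @return An object of class `opm_epochs`: `data` (trials x channels x
#'   samples), `times`, `rate`, `array`, `baseline`, and a `provenance`
#'   tibble recording every event's fate.
#' @export
epoch_and_baseline <- function(rec, events = NULL, tmin = -0.2, tmax = 0.5,
                               baseline = c(-0.1, 0)) {
  events <- events %||% rec$events
  ns <- ncol(rec$data)
  i_min <- round(tmin * rec$rate)
  len <- round((tmax - tmin) * rec$rate)
  times <- (i_min + seq_len(len) - 1) / rec$rate
  bl_mask <- times >= baseline[1] & times < baseline[2]
  if (!any(bl_mask)) abort("Baseline window contains no samples.")

  onsets <- events$sample
  kept <- logical(length(onsets)); reason <- rep(NA_character_, length(onsets))
  slices <- list()
  for (i in seq_along(onsets)) {
    i0 <- onsets[i] + i_min
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > ns) { reason[i] <- "edge"; next }
    t_on <- (onsets[i] - 1) / rec$rate
    if (nrow(rec$bad_segments) &&
        any(rec$bad_segments$start_s < t_on + tmax &
            rec$bad_segments$end_s > t_on + tmin)) {
      reason[i] <- "artefact"; next
    }
    kept[i] <- TRUE
    slices[[length(slices) + 1L]] <- rec$data[, i0:i1, drop = FALSE]
  }
  if (!length(slices)) abort("No trials survive epoching.")
  data <- array(NA_real_, c(length(slices), nrow(rec$data), len))
  for (j in seq_along(slices)) {
    seg <- slices[[j]]
    data[j, , ] <- seg - rowMeans(seg[, bl_mask, drop = FALSE])
  }
  structure(list(
    data = data, times = times, rate = rec$rate, array = rec$array,
    baseline = baseline,
    provenance = tibble(onset_sample = onsets, kept = kept, reason = reason)
  ), class = "opm_epochs")
}

#' @export
print.opm_epochs <- function(x, ...) {
  cat(sprintf("<opm_epochs> %d trials x %d channels x %d samples (%.3f..%.3f s) at %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times) + 1 / x$rate, x$rate))
  dropped <- sum(!x$provenance$kept)
  if (dropped) cat(sprintf("  dropped %d of %d events\n", dropped,
                           nrow(x$provenance)))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

#' Equalise trial counts across conditions
#'
#' Uniform random subsample without replacement to `n` trials per condition,
#' deterministic given `seed`. Errors if any condition has fewer than `n`
#' good trials.
#'
#' @param epochs_list named list of `opm_epochs`.
#' @param n trials to keep per condition (default 525).
#' @param seed integer seed.
#' @return List of subsampled `opm_epochs`.
#' @export
equalize_trials <- function(epochs_list, n = 525, seed = 1L) {
  counts <- vapply(epochs_list, n_trials, integer(1))
  short <- counts < n
  if (any(short)) {
    abort(sprintf("Condition(s) %s have fewer than %d good trials (%s).",
                  paste(names(epochs_list)[short], collapse = ", "), n,
                  paste(counts[short], collapse = ", ")),
          class = "opmpipe_trial_shortfall")
  }
  withr::with_seed(seed, {
    purrr::map(epochs_list, function(ep) {
      keep <- if (n_trials(ep) == n) seq_len(n) else sort(sample.int(n_trials(ep), n))
      ep$data <- ep$data[keep, , , drop = FALSE]
      kept_rows <- which(ep$provenance$kept)
      drop_rows <- setdiff(kept_rows, kept_rows[keep])
      ep$provenance$kept[drop_rows] <- FALSE
      ep$provenance$reason[drop_rows] <- "equalized_out"
      ep
    })
  })
}

#' Average epochs into a sensor-level evoked response
#'
#' @param epochs an `opm_epochs`.
#' @return An object of class `opm_evoked`: `data` (channels x samples,
#'   Tesla), `times`, `rate`, `array`, `n_trials`.
#' @export
evoked_average <- function(epochs) {
  avg <- apply(epochs$data, c(2, 3), mean)
  structure(list(data = avg, times = epochs$times, rate = epochs$rate,
                 array = epochs$array, n_trials = n_trials(epochs)),
            class = "opm_evoked")
}

#' @method tidy opm_evoked
#' @export
tidy.opm_evoked <- function(x, ...) {
  purrr::map(seq_len(nrow(x$data)), function(i) {
    tibble(channel = x$array$channel_names[i], time = x$times,
           field = x$data[i, ])
  }) |> bind_rows()
}
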