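# Domain types for the synthetic OPM recording generator: the remnant room
# field, the sensor noise model, the stimulus train and dipole sources.

#' Affine model of the remnant field inside a shielded room
#'
#' Degaussed, OPM-optimised shielded rooms retain a static remnant field of
#' order 1.5 nT at the room centre, with a spatial gradient that grows away
#' from the centre. The generator models this field as affine in position:
#' `B(p) = B0 + G (p - origin)`. An affine profile is the minimal model that
#' produces movement artefacts when sensors translate and rotate through it;
#' the true room field is nonlinear in space, so this is a deliberate
#' simplification (documented in the methods vignette).
#'
#' @param B0 3-vector, Tesla: remnant field at `origin`. The default has
#'   magnitude 1.5 nT.
#' @param G 3x3 matrix, Tesla per metre: constant spatial gradient tensor.
#'   The default's largest singular value is 5 nT/m, so a 10 cm displacement
#'   along the steepest direction changes the measured field by 500 pT
#'   (within the 100-1000 pT scale expected of a standing participant).
#' @param origin 3-vector, metres: point at which the field equals `B0`.
#' @return An object of class `room_field_model`.
#' @export
room_field_model <- function(B0 = 1.5e-9 * normalize3(c(0.5, -0.3, 0.81)),
                             G = matrix(c(3.0, 0.5, 0.3,
                                          0.5, 4.0, 0.4,
                                          0.3, 0.4, 5.0) * 1e-9, 3, 3),
                             origin = c(0, 0, 0)) {
  stopifnot(length(B0) == 3, all(dim(G) == c(3, 3)), length(origin) == 3)
  structure(list(B0 = as.numeric(B0), G = G, origin = as.numeric(origin)),
            class = "room_field_model")
}

#' Evaluate the room field at one or more positions
#'
#' @param model a [room_field_model()].
#' @param position a 3-vector or an n x 3 matrix of positions (metres).
#' @return A 3-vector or n x 3 matrix of field values (Tesla).
#' @export
room_field_at <- function(model, position) {
  if (is.null(dim(position))) {
    model$B0 + drop(model$G %*% (position - model$origin))
  } else {
    d <- sweep(position, 2, model$origin)
    sweep(d %*% t(model$G), 2, model$B0, `+`)
  }
}

#' Sensor noise and interference model
#'
#' @param white_density white sensor-noise amplitude spectral density,
#'   Tesla per sqrt(Hz). Default 15 fT/sqrt(Hz), typical of second-generation
#'   zero-field magnetometers between 1 and 100 Hz.
#' @param line_components list of `c(frequency_hz, amplitude_tesla)` narrowband
#'   interference lines. The default covers 50 Hz mains plus harmonics and the
#'   120 Hz / 83 Hz lines injected by an optical motion-capture camera system.
#' @param clip_limit dynamic range of the magnetometer, Tesla. Measurements
#'   beyond `+/- clip_limit` are invalid; default 5.56 nT.
#' @return An object of class `opm_noise_model`.
#' @export
noise_model <- function(white_density = 15e-15,
                        line_components = list(c(50, 1.0e-12), c(100, 0.4e-12),
                                               c(150, 0.25e-12), c(120, 0.6e-12),
                                               c(83, 0.4e-12)),
                        clip_limit = 5.56e-9) {
  stopifnot(white_density >= 0, clip_limit > 0)
  for (lc in line_components) {
    stopifnot(length(lc) == 2, lc[1] > 0, lc[2] >= 0)
  }
  structure(list(white_density = white_density,
                 line_components = line_components,
                 clip_limit = clip_limit),
            class = "opm_noise_model")
}

#' Regular auditory stimulus train
#'
#' Tone onsets at a fixed inter-stimulus interval, emulating a standard
#' auditory evoked-field paradigm (70 ms tones, 0.5 s ISI, no jitter).
#'
#' @param n_tones number of tones.
#' @param isi inter-stimulus interval, seconds.
#' @param tone_duration tone duration, seconds.
#' @param t_start onset of the first tone, seconds.
#' @return An object of class `stimulus_train` with strictly increasing onsets.
#' @export
stimulus_train <- function(n_tones = 570, isi = 0.5, tone_duration = 0.070,
                           t_start = 1.0) {
  stopifnot(n_tones >= 1, isi > 0, tone_duration > 0)
  structure(list(onsets = t_start + (seq_len(n_tones) - 1) * isi,
                 tone_duration = tone_duration, isi = isi, n_tones = n_tones),
            class = "stimulus_train")
}

#' Canonical auditory evoked waveform
#'
#' Sum of Gaussian-windowed deflections emulating the M50 / M100 / M200
#' complex of the auditory evoked field: a small positive deflection near
#' 50 ms, the dominant (negative) M100 near 100 ms, and an intermediate
#' positive M200 near 200 ms. The waveform is causal (identically zero before
#' stimulus onset).
#'
#' @param t time in seconds relative to stimulus onset (vectorised).
#' @param components data frame with columns `latency` (s), `width` (s,
#'   Gaussian sigma), `amplitude` (A m, > 0) and `sign` (+1/-1).
#' @return Dipole moment amplitude in Ampere-metres at each `t`.
#' @export
evoked_waveform <- function(t, components = evoked_components()) {
  stopifnot(all(components$width > 0))
  out <- numeric(length(t))
  for (i in seq_len(nrow(components))) {
    out <- out + components$sign[i] * components$amplitude[i] *
      exp(-(t - components$latency[i])^2 / (2 * components$width[i]^2))
  }
  out[t < 0] <- 0
  out
}

#' Default evoked-response components
#'
#' Latencies at 50, 100 and 200 ms with alternating polarity and the M100
#' largest. The moment amplitudes are scaled so that, forward-projected
#' through the default sensor array and spherical head model, the strongest
#' sensor-level deflection lies in the 50-150 fT range typical of auditory
#' evoked fields.
#'
#' @param scale overall multiplicative factor on the moment amplitudes.
#' @return A tibble with columns `latency`, `width`, `amplitude`, `sign`.
#' @export
evoked_components <- function(scale = 1) {
  tibble(
    latency = c(0.050, 0.100, 0.200),
    width = c(0.010, 0.016, 0.030),
    amplitude = scale * c(2.5e-9, 8e-9, 4.5e-9),
    sign = c(1, -1, 1)
  )
}

#' Current dipole source
#'
#' @param position 3-vector, metres, head frame.
#' @param orientation 3-vector dipole moment direction (normalised
#'   internally; must be non-zero).
#' @param waveform function of peristimulus time (s) returning the moment in
#'   Ampere-metres, or `NULL` for the default evoked waveform.
#' @param trial_locked logical; if `TRUE` the waveform repeats at every
#'   stimulus onset.
#' @return An object of class `dipole_source`.
#' @export
dipole_source <- function(position, orientation, waveform = NULL,
                          trial_locked = TRUE) {
  stopifnot(length(position) == 3, length(orientation) == 3)
  n <- sqrt(sum(orientation^2))
  if (n < 1e-12) abort("`orientation` must be non-zero.")
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / n,
                 waveform = waveform %||% evoked_waveform,
                 trial_locked = isTRUE(trial_locked)),
            class = "dipole_source")
}
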