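# The multichannel magnetometer recording container.

#' Construct an OPM recording container
#'
#' The central sensor-space container: a channels x samples matrix of
#' magnetic field measurements (Tesla) plus sampling rate, channel geometry,
#' stimulus events, an append-only history of processing stages, and a table
#' of bad segments.
#'
#' @param data channels x samples numeric matrix, Tesla.
#' @param rate sampling rate, Hz.
#' @param array the `opm_sensor_array` describing channel geometry.
#' @param events tibble with columns `label` and `sample` (1-based).
#' @param history list of processing-stage records.
#' @param bad_segments tibble with columns `start_s`, `end_s`, `reason`.
#' @return An object of class `opm_recording`.
#' @export
new_recording <- function(data, rate, array,
                          events = tibble(label = character(), sample = integer()),
                          history = list(),
                          bad_segments = tibble(start_s = numeric(),
                                                end_s = numeric(),
                                                reason = character())) {
  stopifnot(is.matrix(data), nrow(data) == n_channels(array))
  structure(list(data = data, rate = rate, array = array, events = events,
                 history = history, bad_segments = bad_segments),
            class = "opm_recording")
}

#' @export
print.opm_recording <- function(x, ...) {
  cat(sprintf("<opm_recording> %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  if (length(x$history)) {
    cat("  history:", paste(vapply(x$history, `[[`, "", "stage"), collapse = " -> "), "\n")
  }
  if (nrow(x$bad_segments)) {
    cat(sprintf("  bad segments: %d (%.1f s total)\n", nrow(x$bad_segments),
                sum(x$bad_segments$end_s - x$bad_segments$start_s)))
  }
  invisible(x)
}

#' @method tidy opm_recording
#' @export
tidy.opm_recording <- function(x, channels = NULL, ...) {
  ch <- channels %||% x$array$channel_names
  idx <- match(ch, x$array$channel_names)
  t <- (seq_len(ncol(x$data)) - 1) / x$rate
  purrr::map2(ch, idx, function(nm, i) {
    tibble(channel = nm, time = t, field = x$data[i, ])
  }) |> bind_rows()
}

record_stage <- function(rec, stage, ...) {
  rec$history <- c(rec$history, list(c(list(stage = stage), list(...))))
  rec
}

rec_times <- function(rec) (seq_len(ncol(rec$data)) - 1) / rec$rate

#' Write / read a recording as a plain-text bundle
#'
#' The on-disk format is a directory containing `data.csv` (samples x
#' channels, Tesla, with a header of channel names), and `meta.json` holding
#' the rate, channel geometry, events, history and bad segments.
#'
#' @param rec an `opm_recording`.
#' @param path directory to create.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `opm_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dat <- as.data.frame(t(rec$data))
  names(dat) <- rec$array$channel_names
  utils::write.csv(dat, file.path(path, "data.csv"), row.names = FALSE)
  meta <- list(
    rate = rec$rate,
    n_sensors = rec$array$n_sensors,
    head_radius = rec$array$head_radius,
    standoff = rec$array$standoff,
    positions = rec$array$positions,
    axes_radial = rec$array$axes[, 1, ],
    axes_tangential = rec$array$axes[, 2, ],
    channel_names = rec$array$channel_names,
    events = rec$events,
    history = rec$history,
    bad_segments = rec$bad_segments
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  dat <- utils::read.csv(file.path(path, "data.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  n <- meta$n_sensors
  axes <- array(NA_real_, c(n, 2, 3))
  axes[, 1, ] <- as.matrix(meta$axes_radial)
  axes[, 2, ] <- as.matrix(meta$axes_tangential)
  array <- structure(list(
    n_sensors = n,
    positions = as.matrix(meta$positions),
    axes = axes,
    channel_names = meta$channel_names,
    gain_flags = setNames(rep("ok", 2 * n), meta$channel_names),
    head_radius = meta$head_radius,
    standoff = meta$standoff
  ), class = "opm_sensor_array")
  events <- as_tibble(meta$events)
  if (!nrow(events)) events <- tibble(label = character(), sample = integer())
  bad <- as_tibble(meta$bad_segments)
  if (!nrow(bad)) bad <- tibble(start_s = numeric(), end_s = numeric(), reason = character())
  m <- t(as.matrix(dat))
  dimnames(m) <- NULL
  new_recording(m, meta$rate, array, events,
                history = meta$history %||% list(), bad_segments = bad)
}
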