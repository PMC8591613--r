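# Heavy end-to-end artefacts are computed once per test run and shared
# across test files.

.opmpipe_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .opmpipe_test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .opmpipe_test_cache)
  }
  get(name, envir = .opmpipe_test_cache, inherits = FALSE)
}

# The three-condition study at the reduced desk scale (60 s per condition,
# 90 channels, 1000 Hz, 7.5 mm scanning grid).
get_study <- function() {
  cached("study", suppressMessages(
    run_study(seed = 1, duration = 60, grid_resolution = 0.0075)))
}

# Moving-condition ablation grid (+/- motion regression x +/- HFC).
get_ablation <- function() {
  cached("ablation", suppressMessages(
    ablation_grid(seed = 1, duration = 60, grid_resolution = 0.0075)))
}

# Regularisation sweep on the moving condition of the cached study.
get_sweep <- function() {
  cached("sweep", suppressMessages(
    lambda_sweep(get_study()$conditions$standing_moving)))
}

# A small clean epochs object: one (or two mirrored) dipole(s) at grid
# points, white sensor noise, no motion artefacts.
make_clean_epochs <- function(array, head, grid, src_index, noise_sd = 2e-15,
                              n_trials = 60, seed = 1, amplitude = 1) {
  times <- seq(-0.2, 0.499, by = 0.001)
  wf <- evoked_waveform(times) * amplitude
  g <- 0
  for (i in src_index) {
    d <- grid$points[i, ] / sqrt(sum(grid$points[i, ]^2))
    o <- c(0, 0.8, 0.6); o <- o - sum(o * d) * d; o <- o / sqrt(sum(o^2))
    g <- g + drop(lead_field(head, array, grid$points[i, ]) %*% o)
  }
  nch <- 2L * array$n_sensors
  dat <- withr::with_seed(seed, {
    out <- array(0, c(n_trials, nch, length(times)))
    for (tr in seq_len(n_trials)) {
      out[tr, , ] <- outer(g, wf) +
        matrix(rnorm(nch * length(times), sd = noise_sd), nch)
    }
    out
  })
  structure(list(data = dat, times = times, rate = 1000, array = array,
                 baseline = c(-0.1, 0),
                 provenance = tibble::tibble(onset_sample = seq_len(n_trials),
                                             kept = TRUE, reason = NA_character_)),
            class = "opm_epochs")
}

# Tiny sensor array (8 channels) for fast recording-level unit tests.
tiny_array <- function() make_sensor_array(n_sensors = 4, seed = 7)

tiny_recording <- function(data, rate, array = tiny_array(), ...) {
  new_recording(data, rate, array, ...)
}
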