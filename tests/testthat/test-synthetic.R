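# Synthetic generator: sensor array geometry, room field, motion, markers,
# evoked waveform and full recordings.

test_that("default sensor array has 90 orthonormal dual-axis channels on the scalp", {
  arr <- make_sensor_array(n_sensors = 45, head_radius = 0.09, seed = 1)
  expect_length(arr$channel_names, 90)
  ax <- channel_axes(arr)
  expect_lt(max(abs(rowSums(ax^2) - 1)), 1e-9)
  for (k in seq_len(45)) {
    expect_lt(abs(sum(arr$axes[k, 1, ] * arr$axes[k, 2, ])), 1e-9)
    # radial axis aligned with the position direction
    d <- arr$positions[k, ] / sqrt(sum(arr$positions[k, ]^2))
    expect_equal(sum(arr$axes[k, 1, ] * d), 1, tolerance = 1e-9)
  }
  expect_equal(unique(round(sqrt(rowSums(arr$positions^2)), 10)), 0.0965)
})

test_that("sensor array is deterministic given the seed and varies otherwise", {
  a <- make_sensor_array(seed = 3)
  b <- make_sensor_array(seed = 3)
  c <- make_sensor_array(seed = 4)
  expect_identical(a, b)
  expect_identical(a$positions, c$positions) # geometry is seed-independent
  expect_false(isTRUE(all.equal(a$axes[, 2, ], c$axes[, 2, ]))) # tangential twist differs
  expect_error(make_sensor_array(head_radius = -1), class = "opmpipe_invalid_geometry")
})

test_that("room field model is affine with the stated defaults", {
  rfm <- room_field_model()
  expect_equal(sqrt(sum(rfm$B0^2)), 1.5e-9, tolerance = 1e-12)
  expect_identical(room_field_at(rfm, rfm$origin), rfm$B0)
  # linearity example: G = diag(1e-9, 0, 0), 0.1 m along x -> (100 pT, 0, 0)
  m <- room_field_model(B0 = c(0, 0, 0), G = diag(c(1e-9, 0, 0)))
  expect_equal(room_field_at(m, c(0.1, 0, 0)), c(1e-10, 0, 0))
  # zero gradient: field independent of position
  m0 <- room_field_model(G = matrix(0, 3, 3))
  expect_equal(room_field_at(m0, c(1, -2, 0.5)), m0$B0)
  # default gradient: 10 cm along the steepest direction gives 100-1000 pT
  steep <- svd(room_field_model()$G)$d[1] * 0.1
  expect_gt(steep, 100e-12)
  expect_lt(steep, 1000e-12)
})

test_that("simulated motion honours ranges, starts at identity and is deterministic", {
  tr <- simulate_motion(60, seed = 1)
  expect_equal(unlist(tr[1, c("x", "y", "z", "pitch", "yaw", "roll")]),
               c(x = 0, y = 0, z = 0, pitch = 0, yaw = 0, roll = 0))
  req <- c(1.0, 0.5, 1.15, 110, 150, 180)
  got <- vapply(c("x", "y", "z", "pitch", "yaw", "roll"),
                function(v) diff(range(tr[[v]])), numeric(1))
  expect_true(all(abs(got - req) / req < 0.15))
  expect_identical(simulate_motion(60, seed = 1), tr)
  expect_false(identical(simulate_motion(60, seed = 2), tr))
  # zero-range limit: still condition
  still <- simulate_motion(10, translation_range = c(0, 0, 0),
                           rotation_range = c(0, 0, 0), seed = 1)
  expect_true(all(as.matrix(still[c("x", "y", "z", "pitch", "yaw", "roll")]) == 0))
})

test_that("constant-velocity trajectory moves exactly v*t", {
  tr <- constant_velocity_trajectory(10, rate = 120, velocity = 0.1)
  i0 <- which(tr$time == 2); i1 <- which(tr$time == 2.5)
  expect_equal(tr$x[i1] - tr$x[i0], 0.05, tolerance = 1e-12)
  expect_true(all(tr$pitch == 0))
})

test_that("marker simulation applies the pose and reproduces occlusion statistics", {
  tr <- simulate_motion(10, seed = 2)
  mk <- simulate_markers(tr, occlusion = c(0, 0.029, 1.24))
  expect_false(anyNA(mk$positions))
  # identity pose: markers constant at the layout
  still <- simulate_motion(5, translation_range = c(0, 0, 0),
                           rotation_range = c(0, 0, 0), seed = 1)
  mk0 <- simulate_markers(still)
  for (k in 1:6) {
    expect_equal(mk0$positions[3, k, ], default_marker_layout()[k, ],
                 tolerance = 1e-12)
  }
  # run-3 emulation: occluded fraction within +/- 20% relative
  tr60 <- simulate_motion(60, seed = 1)
  mk3 <- simulate_markers(tr60, occlusion = c(0.089, 0.029, 1.24), seed = 5)
  frac <- mean(is.na(mk3$positions[, , 1]))
  expect_gt(frac, 0.089 * 0.8)
  expect_lt(frac, 0.089 * 1.2)
  expect_error(simulate_markers(tr, layout = cbind(1:6, 1:6 * 2, 1:6 * 3)),
               class = "opmpipe_degenerate_rigid_body")
})

test_that("evoked waveform is causal with its largest deflection at the M100 latency", {
  t <- seq(-0.2, 0.5, by = 0.001)
  w <- evoked_waveform(t)
  expect_true(all(w[t < 0] == 0))
  expect_equal(t[which.max(abs(w))], 0.100)
  # alternating polarity: M50 positive, M100 negative, M200 positive
  expect_gt(evoked_waveform(0.05), 0)
  expect_lt(evoked_waveform(0.10), 0)
  expect_gt(evoked_waveform(0.20), 0)
})

test_that("forward-projected evoked deflection lies in the 50-150 fT range", {
  arr <- make_sensor_array(seed = 11)
  hm <- head_model()
  srcs <- auditory_sources()
  t <- seq(0, 0.3, by = 0.001)
  g <- vapply(srcs, function(s) drop(lead_field(hm, arr, s$position) %*% s$orientation),
              numeric(90))
  peak <- max(abs(g %*% t(vapply(srcs, function(s) s$waveform(t), numeric(length(t))))))
  expect_gt(peak, 50e-15)
  expect_lt(peak, 150e-15)
})

test_that("recording equals the forward projection for a still pose without noise", {
  arr <- make_sensor_array(n_sensors = 10, seed = 2)
  hm <- head_model()
  still <- simulate_motion(4, translation_range = c(0, 0, 0),
                           rotation_range = c(0, 0, 0), seed = 1)
  src <- auditory_sources()[[1]]
  stim <- stimulus_train(n_tones = 5, t_start = 0.5)
  nz <- noise_model(white_density = 0, line_components = list())
  sim <- simulate_recording(arr, still, room_field_model(), list(src), stim,
                            nz, hm, rate = 500, seed = 1)
  g <- drop(lead_field(hm, arr, src$position) %*% src$orientation)
  t <- (seq_len(ncol(sim$recording$data)) - 1) / 500
  neural <- outer(g, drop(sim$ground_truth$source_series))
  # artefact term is constant in time for a still pose
  resid <- sim$recording$data - neural
  expect_lt(max(abs(resid - resid[, 1])), 1e-20)
})

test_that("artefact obeys linear gradient arithmetic for a pure translation", {
  # one sensor with its radial axis along +x, translated 0.1 m through a
  # 1 nT/m gradient: peak-to-peak artefact is exactly 100 pT
  arr <- make_sensor_array(n_sensors = 4, seed = 1)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 0))
  arr$positions <- 0.0965 * dirs
  for (k in 1:4) {
    arr$axes[k, 1, ] <- dirs[k, ]
    t1 <- if (abs(dirs[k, 2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    t1 <- t1 - sum(t1 * dirs[k, ]) * dirs[k, ]
    arr$axes[k, 2, ] <- t1 / sqrt(sum(t1^2))
  }
  room <- room_field_model(B0 = c(0, 0, 0), G = diag(c(1e-9, 0, 0)))
  tr <- constant_velocity_trajectory(4, velocity = 0.025, direction = c(1, 0, 0))
  nz <- noise_model(white_density = 0, line_components = list())
  sim <- simulate_recording(arr, tr, room, list(), stimulus_train(2), nz,
                            head_model(), rate = 200, seed = 1)
  art <- sim$ground_truth$artefact[1, ] # radial-x channel
  travelled <- 0.025 * (ncol(sim$recording$data) - 1) / 200
  expect_equal(diff(range(art)), 1e-9 * travelled, tolerance = 1e-9)
  expect_equal(travelled, 0.1, tolerance = 0.01) # ~0.1 m excursion, ~100 pT
})

test_that("recordings are superposable in their sources and deterministic", {
  arr <- make_sensor_array(n_sensors = 8, seed = 2)
  hm <- head_model()
  tr <- simulate_motion(4, seed = 3,
                        translation_range = c(0.2, 0.1, 0.2),
                        rotation_range = c(20, 30, 30))
  stim <- stimulus_train(n_tones = 5, t_start = 0.5)
  nz <- noise_model()
  srcs <- auditory_sources()
  simAB <- simulate_recording(arr, tr, room_field_model(), srcs, stim, nz, hm,
                              rate = 500, seed = 9)
  simA <- simulate_recording(arr, tr, room_field_model(), srcs[1], stim, nz, hm,
                             rate = 500, seed = 9)
  simB <- simulate_recording(arr, tr, room_field_model(), srcs[2], stim, nz, hm,
                             rate = 500, seed = 9)
  sim0 <- simulate_recording(arr, tr, room_field_model(), list(), stim, nz, hm,
                             rate = 500, seed = 9)
  # superposition: y(A+B) = y(A) + y(B) - y(none), identical noise seeds
  expect_equal(simAB$recording$data,
               simA$recording$data + simB$recording$data - sim0$recording$data,
               tolerance = 1e-12)
  # determinism
  sim2 <- simulate_recording(arr, tr, room_field_model(), srcs, stim, nz, hm,
                             rate = 500, seed = 9)
  expect_identical(simAB$recording$data, sim2$recording$data)
})

test_that("movement artefact energy is concentrated below 6 Hz", {
  cfg <- preset_config("standing_moving", duration = 30)
  arr <- make_sensor_array(seed = cfg$seeds$array)
  tr <- simulate_motion(30, smoothness_cutoff = cfg$smoothness_cutoff,
                        seed = cfg$seeds$motion)
  nz <- noise_model(white_density = 0, line_components = list())
  sim <- simulate_recording(arr, tr, room_field_model(), list(),
                            stimulus_train(5), nz, head_model(),
                            rate = 500, seed = 1)
  art <- sim$ground_truth$artefact
  for (ch in c(1, 45, 90)) {
    x <- art[ch, ] - mean(art[ch, ])
    X <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * 500 / length(x)
    f <- pmin(f, 500 - f)
    expect_gt(sum(X[f < 6]) / sum(X), 0.95)
  }
})

test_that("clipping flags channels and warns when more than half the data clip", {
  arr <- make_sensor_array(n_sensors = 4, seed = 1)
  tr <- constant_velocity_trajectory(2, velocity = 0)
  room <- room_field_model(B0 = c(0, 0, 0), G = matrix(0, 3, 3))
  # noise far beyond the (deliberately tiny) dynamic range clips everywhere
  nz <- noise_model(white_density = 15e-15, line_components = list(),
                    clip_limit = 1e-16)
  expect_warning(
    sim <- simulate_recording(arr, tr, room, list(), stimulus_train(2), nz,
                              head_model(), rate = 200, seed = 1, clip = TRUE),
    "dynamic range")
  expect_true(any(sim$recording$array$gain_flags == "clipped"))
  expect_lte(max(abs(sim$recording$data)), nz$clip_limit)
})

test_that("mocap CSV round-trips marker data including occlusion blanks", {
  tr <- simulate_motion(5, seed = 4)
  mk <- simulate_markers(tr, occlusion = c(0.05, 0.03, 0.5), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_mocap_csv(mk, path)
  back <- read_mocap_csv(path)
  expect_equal(back$positions, mk$positions, tolerance = 1e-9)
  expect_equal(back$rate, mk$rate, tolerance = 1e-6)
})

test_that("recording container round-trips through the plain-text bundle", {
  arr <- make_sensor_array(n_sensors = 4, seed = 1)
  rec <- new_recording(matrix(rnorm(8 * 50), 8, 50) * 1e-12, 250, arr,
                       events = tibble::tibble(label = "tone", sample = c(10L, 30L)))
  path <- tempfile()
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$rate, rec$rate)
  expect_equal(back$events$sample, rec$events$sample)
  expect_equal(channel_axes(back$array), channel_axes(rec$array), tolerance = 1e-12)
})
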