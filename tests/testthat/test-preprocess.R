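# Interference-suppression cascade and epoching.

test_that("downsampling decimates cleanly and suppresses aliases", {
  arr <- tiny_array()
  rate <- 6000
  t <- (0:59999) / rate
  dat <- matrix(1e-12 * sin(2 * pi * 10 * t), 8, length(t), byrow = TRUE)
  rec <- tiny_recording(dat, rate, arr,
                        events = tibble::tibble(label = "tone", sample = 6001L))
  out <- downsample(rec, 1000)
  expect_equal(ncol(out$data), 10000)
  expect_equal(out$rate, 1000)
  expect_equal(out$events$sample, 1001L)
  # identity when target equals the rate
  same <- downsample(rec, 6000)
  expect_identical(same$data, rec$data)
  expect_error(downsample(rec, 12000), class = "opmpipe_upsampling")
  # a 700 Hz component must not alias into the 1000 Hz record
  dat2 <- matrix(1e-12 * sin(2 * pi * 700 * t), 8, length(t), byrow = TRUE)
  out2 <- downsample(tiny_recording(dat2, rate, arr), 1000)
  mid <- 1000:9000
  expect_lt(max(abs(out2$data[1, mid])), 0.01 * 1e-12)
  # the passband is untouched: 10 Hz survives decimation
  expect_lt(max(abs(out$data[1, mid] - 1e-12 * sin(2 * pi * 10 * (mid - 1) / 1000))),
            1e-3 * 1e-12)
})

test_that("windowed motion regression removes exactly-linear artefacts and
           leaves orthogonal signals untouched", {
  arr <- tiny_array()
  rate <- 100
  n <- 3000 # 30 s
  t <- (0:(n - 1)) / rate
  # regressors at exact multiples of 0.1 Hz: integer cycles per 10 s window,
  # hence exactly orthogonal (in every window) to the 25 Hz tone below
  reg <- cbind(x = sin(2 * pi * 0.1 * t), y = cos(2 * pi * 0.2 * t),
               z = sin(2 * pi * 0.3 * t + 1), pitch = cos(2 * pi * 0.4 * t),
               yaw = sin(2 * pi * 0.5 * t), roll = cos(2 * pi * 0.6 * t))
  # channel 1 = 3.0 * x(t): residual RMS < 1e-10 of input RMS
  dat <- matrix(0, 8, n)
  dat[1, ] <- 3.0 * reg[, "x"]
  dat[2, ] <- sin(2 * pi * 25 * t)
  rec <- tiny_recording(dat, rate, arr)
  out <- regress_motion(rec, reg, window_s = 10)
  expect_lt(sqrt(mean(out$data[1, ]^2)), 1e-10 * sqrt(mean(dat[1, ]^2)))
  expect_equal(out$data[2, ], dat[2, ], tolerance = 1e-10)
  # window bookkeeping: 300 s record, 10 s windows, 50% overlap -> 59 windows
  rec300 <- tiny_recording(matrix(rnorm(8 * 30000, sd = 1e-12), 8), 100, arr)
  reg300 <- matrix(rnorm(30000 * 6), ncol = 6, dimnames = list(NULL, colnames(reg)))
  out300 <- regress_motion(rec300, reg300, window_s = 10)
  expect_equal(nrow(attr(out300, "windows")), 59)
})

test_that("still-window regression falls back to the intercept and is flagged", {
  arr <- tiny_array()
  n <- 2000
  dat <- matrix(rnorm(8 * n, sd = 1e-12), 8, n)
  rec <- tiny_recording(dat, 100, arr)
  reg <- matrix(0, n, 6, dimnames = list(NULL, c("x", "y", "z", "pitch", "yaw", "roll")))
  out <- regress_motion(rec, reg, window_s = 10)
  info <- attr(out, "windows")
  expect_true(all(!info$motion_used))
  # intercept-only: each window only loses its mean, so the data keep their
  # fluctuations (no tracking noise injected)
  expect_gt(stats::cor(out$data[1, ], dat[1, ] - mean(dat[1, ])), 0.999)
})

test_that("homogeneous field correction removes uniform fields exactly and
           retains dipolar topographies", {
  arr <- make_sensor_array(seed = 11)
  A <- channel_axes(arr)
  n <- 200
  U <- matrix(rnorm(3 * n, sd = 1e-9), 3, n)
  rec <- new_recording(A %*% U, 1000, arr)
  out <- homogeneous_field_correction(rec)
  expect_lt(max(abs(out$data)), 1e-12 * max(abs(rec$data)))
  expect_equal(attr(out, "hfc_field"), U, tolerance = 1e-9)
  # single sample example: u = (1, 0, 0) nT removed exactly
  rec1 <- new_recording(A %*% matrix(c(1e-9, 0, 0)), 1000, arr)
  out1 <- homogeneous_field_correction(rec1)
  expect_lt(max(abs(drop(attr(out1, "hfc_field")) - c(1e-9, 0, 0))), 1e-18)
  # dipolar topography from a simulated source: >= 90% energy retained
  src <- auditory_sources()[[1]]
  g <- drop(lead_field(head_model(), arr, src$position) %*% src$orientation)
  rec2 <- new_recording(matrix(g, ncol = 1), 1000, arr)
  out2 <- homogeneous_field_correction(rec2)
  expect_gte(sum(out2$data^2) / sum(g^2), 0.90)
})

test_that("spectral interpolation flattens line peaks and spares the rest", {
  arr <- tiny_array()
  rate <- 1000
  n <- 60000
  t <- (0:(n - 1)) / rate
  set.seed(8)
  noise <- matrix(rnorm(8 * n, sd = 1e-13), 8, n)
  line <- 1e-11 * sin(2 * pi * 50 * t) # 100x the noise scale
  rec <- tiny_recording(noise, rate, arr)
  rec$data[1, ] <- noise[1, ] + line
  out <- spectral_interpolation(rec, targets = 50)
  psd_out <- welch_psd(out$data[1, ], rate)
  at50 <- function(p) mean(p$power[p$freq >= 49.5 & p$freq <= 50.5])
  flank <- function(p) mean(p$power[(p$freq >= 48 & p$freq < 49) |
                                      (p$freq > 51 & p$freq <= 52)])
  # post-hoc PSD at 50 Hz within 3 dB of the flanking bands
  expect_lt(abs(10 * log10(at50(psd_out) / flank(psd_out))), 3)
  # non-target frequencies within 10% of the uncontaminated PSD
  off_target <- psd_out$freq > 5 & psd_out$freq < 45
  expect_lt(max(abs(psd_out$power[off_target] /
                      welch_psd(noise[1, ], rate)$power[off_target] - 1)), 0.1)
})

test_that("zero-phase recording filters behave at DC, peaks and band edges", {
  arr <- tiny_array()
  rate <- 1000
  n <- 20000
  t <- (0:(n - 1)) / rate
  # DC offset through the 2 Hz order-5 high-pass
  rec <- tiny_recording(matrix(1e-11, 8, n), rate, arr)
  hp <- filter_zero_phase(rec, "highpass", 2, 5)
  expect_lt(abs(mean(hp$data[1, ])), 1e-6 * 1e-11)
  # symmetric Gaussian bump through the 40 Hz low-pass keeps its peak sample
  bump <- exp(-(t - 10)^2 / (2 * 0.05^2))
  rec2 <- tiny_recording(matrix(bump * 1e-12, 8, n, byrow = TRUE), rate, arr)
  lp <- filter_zero_phase(rec2, "lowpass", 40, 6)
  expect_equal(which.max(lp$data[1, ]), which.max(bump))
  # 6 Hz through the 2 Hz order-5 high-pass: preserved within 2%
  s6 <- sin(2 * pi * 6 * t)
  rec3 <- tiny_recording(matrix(s6 * 1e-12, 8, n, byrow = TRUE), rate, arr)
  hp6 <- filter_zero_phase(rec3, "highpass", 2, 5)
  mid <- 2000:18000
  expect_lt(max(abs(hp6$data[1, mid] - 1e-12 * s6[mid])), 0.02 * 1e-12)
  expect_error(filter_zero_phase(rec3, "lowpass", 600, 4))
})

test_that("artefact detection flags range, step and HF-noise chunks with reasons", {
  arr <- tiny_array()
  rate <- 200
  n <- 60 * rate # 12 chunks of 5 s
  base <- matrix(rnorm(8 * n, sd = 1e-13), 8, n)
  rec <- tiny_recording(base, rate, arr)
  # constant (clean) data -> no flags
  out0 <- detect_artefact_segments(tiny_recording(matrix(1e-12, 8, n), rate, arr))
  expect_equal(nrow(out0$bad_segments), 0)
  # (i) a 200 pT ramp on one channel within chunk 3
  dat <- base
  idx <- (2 * 5 * rate + 1):(3 * 5 * rate)
  dat[3, idx] <- dat[3, idx] + seq(0, 200e-12, length.out = length(idx))
  out1 <- detect_artefact_segments(tiny_recording(dat, rate, arr))
  expect_true(any(out1$bad_segments$start_s == 10 & grepl("range", out1$bad_segments$reason)))
  # (iii) a simultaneous 150 pT step on all channels in chunk 7
  dat2 <- base
  dat2[, (6 * 5 * rate + 100):n] <- dat2[, (6 * 5 * rate + 100):n] + 150e-12
  out2 <- detect_artefact_segments(tiny_recording(dat2, rate, arr))
  hit <- out2$bad_segments[out2$bad_segments$start_s == 30, ]
  expect_gt(nrow(hit), 0)
  expect_true(any(grepl("range|step", hit$reason)))
  # (ii) intermittent high-frequency burst in chunk 5
  dat3 <- base
  burst <- (4 * 5 * rate + 1):(4 * 5 * rate + rate)
  dat3[2, burst] <- dat3[2, burst] + 2e-12 * sin(2 * pi * 90 * seq_along(burst) / rate)
  out3 <- detect_artefact_segments(tiny_recording(dat3, rate, arr), hf_band = c(80, 100))
  expect_true(any(out3$bad_segments$start_s == 20 & grepl("hf_noise", out3$bad_segments$reason)))
})

test_that("epoching cuts 700-sample baseline-zero trials and drops bad ones", {
  arr <- tiny_array()
  rate <- 1000
  n <- 10000
  dat <- matrix(rnorm(8 * n, sd = 1e-13), 8, n)
  events <- tibble::tibble(label = "tone", sample = c(50L, 1001L, 3001L, 5001L, 9901L))
  rec <- tiny_recording(dat, rate, arr, events = events)
  rec$bad_segments <- tibble::tibble(start_s = 4.9, end_s = 5.1, reason = "range")
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[3], 700)
  # events at 50 (too early), 9901 (too late) and 5001 (bad segment) dropped
  expect_equal(sum(ep$provenance$kept), 2)
  expect_equal(ep$provenance$reason[c(1, 5)], c("edge", "edge"))
  expect_equal(ep$provenance$reason[4], "artefact")
  # baseline mean is exactly removed
  bl <- ep$times >= -0.1 & ep$times < 0
  for (tr in 1:2) expect_lt(max(abs(rowMeans(ep$data[tr, , bl]))), 1e-15)
})

test_that("trial equalisation subsamples deterministically and errors on shortfall", {
  arr <- tiny_array()
  rate <- 500
  n <- 40 * rate
  dat <- matrix(rnorm(8 * n, sd = 1e-13), 8, n)
  events <- tibble::tibble(label = "tone",
                           sample = as.integer(seq(500, n - 500, by = 250)))
  rec <- tiny_recording(dat, rate, arr, events = events)
  ep <- epoch_and_baseline(rec)
  lst <- list(a = ep, b = ep)
  eq <- equalize_trials(lst, n = 50, seed = 3)
  expect_equal(vapply(eq, opmpipe:::n_trials, integer(1)), c(a = 50L, b = 50L))
  eq2 <- equalize_trials(lst, n = 50, seed = 3)
  expect_identical(eq$a$data, eq2$a$data)
  # n equal to the available count keeps everything in order
  all_eq <- equalize_trials(lst, n = opmpipe:::n_trials(ep), seed = 1)
  expect_identical(all_eq$a$data, ep$data)
  expect_error(equalize_trials(lst, n = 1e6, seed = 1),
               class = "opmpipe_trial_shortfall")
})

test_that("every stage commutes with positive channel scaling and replays
           bit-identically from its history", {
  arr <- tiny_array()
  rate <- 500
  n <- 15 * rate
  t <- (0:(n - 1)) / rate
  set.seed(5)
  dat <- matrix(rnorm(8 * n, sd = 1e-12), 8, n) +
    outer(rep(2e-11, 8), sin(2 * pi * 0.2 * t))
  reg <- cbind(x = sin(2 * pi * 0.2 * t), y = 0, z = 0, pitch = 0, yaw = 0, roll = 0)
  scale <- 3.7
  run_stages <- function(d) {
    rec <- tiny_recording(d, rate, arr)
    rec <- regress_motion(rec, reg, window_s = 5)
    rec <- homogeneous_field_correction(rec)
    rec <- spectral_interpolation(rec, targets = 50)
    rec <- filter_zero_phase(rec, "highpass", 2, 5)
    filter_zero_phase(rec, "lowpass", 40, 6)
  }
  a <- run_stages(dat)
  b <- run_stages(dat * scale)
  expect_equal(b$data, a$data * scale, tolerance = 1e-9)
  # replaying the recorded history reproduces the output bit-identically
  expect_identical(run_stages(dat)$data, a$data)
  expect_equal(vapply(a$history, `[[`, "", "stage"),
               c("regress_motion", "hfc", "spectral_interpolation",
                 "filter_highpass", "filter_lowpass"))
})
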