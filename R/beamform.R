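# LCMV beamforming with symmetric dipole pairs: covariance estimation,
# spatial filters, neural activity index mapping, ROI virtual channels,
# pointwise statistics and Welch PSD diagnostics.

#' Sensor covariance from unaveraged single-trial data
#'
#' Mean over trials and window samples of the outer product of demeaned
#' channel vectors; channels are demeaned per trial over the window.
#'
#' @param epochs an `opm_epochs`.
#' @param window time window in seconds, half-open (default `c(0, 0.5)`,
#'   i.e. the post-stimulus interval).
#' @return An object of class `opm_covariance`: `C` (channels x channels,
#'   Tesla squared), `window`, `n_trials`, `n_samples`.
#' @export
covariance <- function(epochs, window = c(0, 0.5)) {
  if (n_trials(epochs) < 2) abort("Need at least 2 trials.")
  mask <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(mask)) abort("Covariance window lies outside the epoch.")
  nch <- dim(epochs$data)[2]
  L <- sum(mask)
  C <- matrix(0, nch, nch)
  for (tr in seq_len(n_trials(epochs))) {
    seg <- epochs$data[tr, , mask, drop = TRUE]
    seg <- seg - rowMeans(seg)
    C <- C + tcrossprod(seg)
  }
  C <- C / (n_trials(epochs) * L)
  C <- (C + t(C)) / 2
  out <- structure(list(C = C, window = window, n_trials = n_trials(epochs),
                        n_samples = L), class = "opm_covariance")
  if (n_trials(epochs) * L < nch) {
    attr(out, "rank_deficient") <- TRUE
    warn("Fewer covariance samples than channels; regularisation required.")
  }
  out
}

reg_covariance <- function(cov, lambda_percent) {
  C <- if (inherits(cov, "opm_covariance")) cov$C else cov
  C + (lambda_percent / 100) * (sum(diag(C)) / nrow(C)) * diag(nrow(C))
}

#' LCMV beamformer weights
#'
#' Linearly constrained minimum-variance spatial filter for a k-column lead
#' field: `W = (L' Creg^-1 L)^-1 L' Creg^-1`, with diagonal loading
#' `Creg = C + (lambda/100) (trace(C)/channels) I`. The unit-gain constraint
#' `W L = I_k` holds by construction; if `L' Creg^-1 L` is singular a
#' pseudo-inverse is used and the result is flagged.
#'
#' @param cov an `opm_covariance` (or plain matrix).
#' @param L channels x k lead field (k = 3 single dipole, k = 6 symmetric
#'   pair).
#' @param lambda_percent regularisation in percent of the mean sensor power
#'   (default 0.1).
#' @return k x channels weight matrix; attribute `pseudo_inverse` flags a
#'   singular constraint system.
#' @export
lcmv_weights <- function(cov, L, lambda_percent = 0.1) {
  Creg <- reg_covariance(cov, lambda_percent)
  if (!all(is.finite(Creg))) abort("Covariance contains non-finite values.")
  CiL <- solve(Creg, L)
  G <- crossprod(L, CiL)
  W <- tryCatch(solve(G, t(CiL)), error = function(e) {
    sv <- svd(G)
    tol <- max(sv$d) * 1e-12
    pos <- sv$d > tol
    Gp <- sv$v[, pos, drop = FALSE] %*% ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
    structure(Gp %*% t(CiL), pseudo_inverse = TRUE)
  })
  W
}

# Internal fast path used by map/sweep code: precomputed Creg^-1.
lcmv_weights_ci <- function(Ci, L) {
  CiL <- Ci %*% L
  G <- crossprod(L, CiL)
  solve(G, t(CiL))
}

# Orthonormal basis of the covariance's principal (non-null) subspace.
# Interference projection such as homogeneous field correction leaves the
# sensor data rank-deficient (an exactly-zero-variance subspace); scanning
# inside the principal subspace keeps the minimum-variance criterion and the
# projected-noise reference meaningful.
cov_subspace <- function(C, tol = 1e-3) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  # directions with variance orders of magnitude below the typical
  # (median) sensor variance are numerically empty, not genuine signal
  keep <- e$values > tol * stats::median(abs(e$values))
  e$vectors[, keep, drop = FALSE]
}

# Reduce a lead field to its magnetically visible column space. In a
# spherical conductor the radial moment direction is silent, so a 3-column
# dipole lead field has rank 2 (a symmetric pair, rank 4); scanning the
# reduced lead field keeps the unit-gain constraint well posed.
reduce_lead_field <- function(L, tol = 1e-8) {
  sv <- svd(L)
  keep <- sv$d > tol * max(sv$d, .Machine$double.xmin)
  if (!any(keep)) return(NULL)
  sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = sum(keep))
}

#' Neural activity index map over a symmetric source grid
#'
#' Scans the grid with the LCMV beamformer (by default as symmetric dipole
#' pairs, which recovers bilateral, highly correlated sources that a
#' single-dipole scan suppresses). Per scanned point: source power is
#' `trace(W C_win W')` with `C_win` estimated in `window`; projected noise
#' is `sigma0^2 trace(W W')` with `sigma0^2` the smallest eigenvalue of the
#' regularised covariance; their ratio is the neural activity index (NAI),
#' which cancels the depth bias of raw beamformer power. Both members of a
#' pair receive the pair's NAI.
#'
#' @param epochs an `opm_epochs`.
#' @param grid an `opm_source_grid`.
#' @param lf m x channels x 3 lead-field array from [lead_field_grid()].
#' @param lambda_percent regularisation (default 0.1).
#' @param window NAI power window, seconds (default `c(0.08, 0.12)`, the
#'   M100 latency range).
#' @param cov_window covariance window for the weights (default
#'   `c(0, 0.5)`).
#' @param paired scan symmetric pairs (default) or single dipoles.
#' @param method `"scalar"` (default): the NAI is the largest generalised
#'   eigenvalue of window power against projected noise over source
#'   orientations — the optimal-orientation scalar beamformer, which resists
#'   the residual depth preference that trace power retains when a deep
#'   symmetric pair can mimic a bilateral superficial pattern; `"trace"`:
#'   trace power over all scanned orientations.
#' @param power_from `"evoked"` (default): window power of the
#'   trial-averaged evoked response (the M100 deflection itself);
#'   `"single_trial"`: demeaned single-trial window covariance.
#' @return An `opm_source_map` tibble: `x`, `y`, `z`, `nai`, `power`,
#'   `noise`, `pair`.
#' @export
nai_map <- function(epochs, grid, lf, lambda_percent = 0.1,
                    window = c(0.08, 0.12), cov_window = c(0, 0.5),
                    paired = TRUE, method = c("scalar", "trace"),
                    power_from = c("evoked", "single_trial")) {
  method <- match.arg(method)
  power_from <- match.arg(power_from)
  cov <- covariance(epochs, cov_window)
  Cw <- if (power_from == "evoked") {
    mask <- epochs$times >= window[1] & epochs$times < window[2]
    if (!any(mask)) abort("NAI window lies outside the epoch.")
    avg <- apply(epochs$data[, , mask, drop = FALSE], c(2, 3), mean)
    tcrossprod(avg) / sum(mask)
  } else {
    covariance(epochs, window)$C
  }
  # beamform inside the data's principal subspace (rank-deficient after
  # interference projection stages such as HFC)
  E <- cov_subspace(cov$C)
  Cr <- crossprod(E, cov$C %*% E)
  Cwr <- crossprod(E, Cw %*% E)
  Creg <- reg_covariance(Cr, lambda_percent)
  Ci <- solve(Creg)
  sigma0 <- min(eigen(Creg, symmetric = TRUE, only.values = TRUE)$values)
  m <- nrow(grid$points)
  nai <- power <- noise <- rep(NA_real_, m)
  pair_id <- rep(NA_integer_, m)
  done <- logical(m)
  pid <- 0L
  for (i in seq_len(m)) {
    if (done[i]) next
    j <- grid$pair_index[i]
    pid <- pid + 1L
    L <- if (paired) pair_lead_field(lf, grid, i) else lf[i, , ]
    L <- reduce_lead_field(crossprod(E, L))
    if (is.null(L)) { done[unique(c(i, j))] <- TRUE; next } # silent point
    W <- lcmv_weights_ci(Ci, L)
    A <- W %*% Cwr %*% t(W)
    B <- sigma0 * tcrossprod(W)
    p <- sum(diag(A))
    nz <- sum(diag(B))
    val <- if (method == "trace") p / nz else {
      max(Re(eigen(solve(B, A), only.values = TRUE)$values))
    }
    members <- if (paired) unique(c(i, j)) else i
    power[members] <- p
    noise[members] <- nz
    nai[members] <- val
    pair_id[members] <- pid
    done[members] <- TRUE
  }
  out <- tibble(x = grid$points[, 1], y = grid$points[, 2],
                z = grid$points[, 3], nai = nai, power = power,
                noise = noise, pair = pair_id)
  class(out) <- c("opm_source_map", class(out))
  attr(out, "window") <- window
  attr(out, "lambda_percent") <- lambda_percent
  attr(out, "resolution") <- grid$resolution
  attr(out, "paired") <- paired
  out
}

#' Spatial focality of a source map
#'
#' Fraction of grid points whose NAI is at least `frac` of the map maximum
#' (larger = less focal). The 75% threshold mirrors common display
#' conventions for beamformer maps.
#'
#' @param map an `opm_source_map`.
#' @param frac threshold as a fraction of the maximum (default 0.75).
#' @return A single number in (0, 1].
#' @export
map_focality <- function(map, frac = 0.75) {
  mean(map$nai >= frac * max(map$nai, na.rm = TRUE), na.rm = TRUE)
}

#' ROI virtual channel via PCA of concatenated beamformer filters
#'
#' Stacks the spatial filters of every grid point in the region of interest
#' row-wise into `F`, forms `M = F C F'` with the sensor covariance `C`,
#' takes the principal eigenvector `v` of `M`, and uses `w = v' F` as the
#' ROI spatial filter. The single-trial virtual channel is `w` applied to
#' the epoched data; polarity is fixed so the averaged series has a positive
#' peak in the 0.08-0.12 s window (making the series invariant to global
#' sensor sign flips). No noise normalisation is applied to the ROI series;
#' a pointwise one-sample t-series across trials is attached instead.
#'
#' @param epochs an `opm_epochs`.
#' @param grid an `opm_source_grid`.
#' @param lf lead-field array.
#' @param roi integer indices (or logical mask) of grid points in the ROI.
#' @param lambda_percent regularisation (default 0.1).
#' @param cov_window covariance window (default `c(0, 0.5)`).
#' @param paired use symmetric-pair filters (default TRUE).
#' @param polarity_window window in which the average peak is made positive.
#' @return An object of class `opm_virtual_channel`: `trials` (trials x
#'   samples), `average`, `t` tibble (`time`, `mean`, `t`, `df`), `weights`
#'   (1 x channels), `times`.
#' @export
roi_virtual_channel <- function(epochs, grid, lf, roi, lambda_percent = 0.1,
                                cov_window = c(0, 0.5), paired = TRUE,
                                polarity_window = c(0.08, 0.12)) {
  if (is.logical(roi)) roi <- which(roi)
  if (!length(roi)) abort("ROI is empty.")
  cov <- covariance(epochs, cov_window)
  if (max(abs(cov$C)) == 0) abort("Covariance is zero.")
  E <- cov_subspace(cov$C)
  Cr <- crossprod(E, cov$C %*% E)
  Creg <- reg_covariance(Cr, lambda_percent)
  Ci <- solve(Creg)
  scanned <- if (paired) {
    keep <- !duplicated(pmin(roi, grid$pair_index[roi]))
    roi[keep]
  } else roi
  Fs <- do.call(rbind, lapply(scanned, function(i) {
    L <- if (paired) pair_lead_field(lf, grid, i) else lf[i, , ]
    L <- reduce_lead_field(crossprod(E, L))
    if (is.null(L)) return(NULL)
    lcmv_weights_ci(Ci, L)
  }))
  M <- Fs %*% Cr %*% t(Fs)
  v <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1]
  w <- drop(v %*% Fs) %*% t(E) # back to channel space
  w <- drop(w)
  ntr <- n_trials(epochs)
  trials <- matrix(NA_real_, ntr, length(epochs$times))
  for (tr in seq_len(ntr)) {
    trials[tr, ] <- drop(w %*% epochs$data[tr, , ])
  }
  avg <- colMeans(trials)
  pol <- epochs$times >= polarity_window[1] & epochs$times < polarity_window[2]
  if (any(pol) && max(avg[pol]) < -min(avg[pol])) {
    w <- -w; trials <- -trials; avg <- -avg
  }
  tt <- pointwise_t(trials)
  structure(list(trials = trials, average = avg,
                 t = tibble(time = epochs$times, mean = avg, t = tt$t,
                            df = tt$df),
                 weights = w, times = epochs$times),
            class = "opm_virtual_channel")
}

#' @export
print.opm_virtual_channel <- function(x, ...) {
  pk <- x$times[which.max(abs(x$average))]
  cat(sprintf("<opm_virtual_channel> %d trials, %d samples; |peak| at %.3f s\n",
              nrow(x$trials), ncol(x$trials), pk))
  invisible(x)
}

#' @method tidy opm_virtual_channel
#' @export
tidy.opm_virtual_channel <- function(x, ...) x$t

#' Pointwise one-sample t-series across trials
#'
#' `t = mean / (sd / sqrt(n))` at every sample, with `df = n - 1`. Samples
#' with zero variance get signed infinity and are flagged.
#'
#' @param trials trials x samples matrix.
#' @return List with `t`, `df`, `zero_variance` (logical per sample).
#' @export
pointwise_t <- function(trials) {
  n <- nrow(trials)
  if (n < 2) abort("Need at least 2 trials.")
  mu <- colMeans(trials)
  s <- apply(trials, 2, sd)
  zero <- s == 0
  t <- ifelse(zero, sign(mu) * Inf, mu / (s / sqrt(n)))
  t[zero & mu == 0] <- 0
  list(t = t, df = n - 1, zero_variance = zero)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments (default 2 s) with
#' 50% overlap, one-sided density normalisation, optionally restricted to a
#' reporting band. Units are input-units squared per Hz.
#'
#' @param x numeric series.
#' @param rate sampling rate, Hz.
#' @param seg_s segment length, seconds.
#' @param overlap fractional overlap between segments.
#' @param band optional `c(lo, hi)` band (Hz) to restrict the output.
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, rate, seg_s = 2, overlap = 0.5, band = NULL) {
  nseg <- round(seg_s * rate)
  if (length(x) < nseg) abort("Series shorter than one PSD segment.")
  if (!is.null(band) && band[2] > rate / 2) {
    abort("Requested band extends above the Nyquist frequency.")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  norm <- rate * sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)] * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2 / norm
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  freq <- (seq_len(nf) - 1) * rate / nseg
  out <- tibble(freq = freq, power = p)
  if (!is.null(band)) out <- out[out$freq >= band[1] & out$freq <= band[2], ]
  out
}

#' Band-average PSD in decibels
#'
#' Convenience for comparing interference levels: `10 log10(mean power)` of
#' a Welch PSD restricted to `band`.
#'
#' @inheritParams welch_psd
#' @param band `c(lo, hi)` in Hz.
#' @return A single number (dB relative to 1 unit^2/Hz).
#' @export
band_power_db <- function(x, rate, band, seg_s = 2, overlap = 0.5) {
  psd <- welch_psd(x, rate, seg_s = seg_s, overlap = overlap, band = band)
  10 * log10(mean(psd$power))
}

#' Apply a sensor-space spatial filter to a continuous recording
#'
#' @param rec an `opm_recording`.
#' @param weights 1 x channels (or length-channels) weight vector, e.g. from
#'   [roi_virtual_channel()].
#' @return Numeric series of length `n_samples`.
#' @export
apply_spatial_filter <- function(rec, weights) {
  drop(matrix(weights, 1) %*% rec$data)
}
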