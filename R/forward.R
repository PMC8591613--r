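# Forward model: homogeneous conducting sphere, symmetric source grid, and
# current-dipole lead fields.

#' Spherical conductor head model
#'
#' An analytic homogeneous conducting sphere. The spherical conductor shares
#' the key structural property of realistic single-shell conductors for MEG:
#' radial dipole moments are magnetically silent outside the conductor, and
#' the external field has a closed form (Sarvas' formula), which keeps the
#' forward model exactly specified and dependency-free.
#'
#' @param centre sphere centre, metres, head frame.
#' @param radius sphere radius, metres (default 0.09, an adult head).
#' @return An object of class `opm_head_model`.
#' @export
head_model <- function(centre = c(0, 0, 0), radius = 0.09) {
  stopifnot_scalar_pos(radius, "radius")
  structure(list(kind = "sphere", centre = as.numeric(centre), radius = radius),
            class = "opm_head_model")
}

#' Symmetric volumetric source grid
#'
#' Axis-aligned lattice of candidate dipole locations clipped to
#' `|p - centre| < clip * radius`, laid out symmetrically about the
#' mid-sagittal plane `x = centre[1]` so every point has an exact mirror
#' partner (points on the plane are their own mirror). The pairing is an
#' involution.
#'
#' @param model an [head_model()].
#' @param resolution lattice spacing, metres (default 0.005).
#' @param clip fraction of the radius to which the grid is clipped (default
#'   0.9, avoiding near-surface numerical blow-up of the lead field).
#' @return An object of class `opm_source_grid`: `points` (m x 3),
#'   `pair_index` (mirror partner of each point), `resolution`.
#' @export
make_grid <- function(model, resolution = 0.005, clip = 0.9) {
  stopifnot_scalar_pos(resolution, "resolution")
  r <- model$radius * clip
  k <- floor(r / resolution)
  if (k < 0 || r < resolution / 2) {
    inform("Grid resolution exceeds the clipped head radius; grid is empty or a single point.")
  }
  offs <- seq(-k, k) * resolution
  pts <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  pts <- sweep(pts, 2, model$centre, `+`)
  keep <- row_norms(sweep(pts, 2, model$centre)) < r
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) inform("Source grid is empty at this resolution.")
  # mirror partner: x -> 2*cx - x; lattice is symmetric so lookup is exact
  key <- function(p) paste(round((p[, 1] - model$centre[1]) / resolution),
                           round((p[, 2] - model$centre[2]) / resolution),
                           round((p[, 3] - model$centre[3]) / resolution))
  mirrored <- pts; mirrored[, 1] <- 2 * model$centre[1] - pts[, 1]
  pair_index <- match(key(mirrored), key(pts))
  structure(list(points = pts, pair_index = pair_index,
                 resolution = resolution, model = model),
            class = "opm_source_grid")
}

#' @export
print.opm_source_grid <- function(x, ...) {
  cat(sprintf("<opm_source_grid> %d points at %.1f mm resolution\n",
              nrow(x$points), 1000 * x$resolution))
  invisible(x)
}

#' Lead field of a current dipole in a conducting sphere
#'
#' Magnetic field of a current dipole inside a homogeneous conducting
#' sphere, evaluated with Sarvas' closed form and projected onto each
#' channel's unit sensitive axis. Columns correspond to unit dipole moments
#' along the three coordinate axes (Tesla per Ampere-metre).
#'
#' @param model an [head_model()].
#' @param array an `opm_sensor_array` (all channels must lie outside the
#'   sphere).
#' @param p dipole position (3-vector, metres), strictly inside the sphere.
#' @return channels x 3 gain matrix.
#' @export
lead_field <- function(model, array, p) {
  r0 <- as.numeric(p) - model$centre
  if (sqrt(sum(r0^2)) >= model$radius) {
    abort("Dipole position must lie strictly inside the sphere.",
          class = "opmpipe_geometry")
  }
  Rm <- sweep(channel_positions(array), 2, model$centre)
  if (any(row_norms(Rm) <= model$radius)) {
    abort("All sensors must lie outside the sphere.",
          class = "opmpipe_geometry")
  }
  sarvas_gain(r0, Rm, channel_axes(array))
}

# Core Sarvas evaluation: dipole at r0, field points Rm (n x 3), projection
# axes (n x 3); all relative to the sphere centre. Returns n x 3 gains.
sarvas_gain <- function(r0, Rm, axes) {
  a <- sweep(Rm, 2, r0) # r - r0
  an <- row_norms(a)
  rn <- row_norms(Rm)
  ar <- rowSums(a * Rm)
  r0r <- drop(Rm %*% r0)
  F_ <- an * (rn * an + rn^2 - r0r)
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gradF <- c1 * Rm - outer(c2, r0)
  out <- matrix(NA_real_, nrow(Rm), 3)
  e <- diag(3)
  for (j in 1:3) {
    cj <- cross3(e[j, ], r0)
    cj_r <- drop(Rm %*% cj)
    Bj <- (MU0 / (4 * pi)) * (outer(F_, cj) - cj_r * gradF) / F_^2
    out[, j] <- rowSums(axes * Bj)
  }
  out
}

#' Lead fields for every point of a source grid
#'
#' @param model an [head_model()].
#' @param array an `opm_sensor_array`.
#' @param grid an `opm_source_grid` (or an m x 3 matrix of positions).
#' @return An m x channels x 3 array of gains.
#' @export
lead_field_grid <- function(model, array, grid) {
  pts <- if (inherits(grid, "opm_source_grid")) grid$points else as.matrix(grid)
  nch <- n_channels(array)
  Rm <- sweep(channel_positions(array), 2, model$centre)
  axes <- channel_axes(array)
  out <- array(NA_real_, c(nrow(pts), nch, 3))
  for (i in seq_len(nrow(pts))) {
    out[i, , ] <- sarvas_gain(pts[i, ] - model$centre, Rm, axes)
  }
  out
}

#' Symmetric-pair lead field
#'
#' Horizontal concatenation of a grid point's gain matrix with its mirror
#' partner's, for scanning pairs of symmetric dipoles across the
#' hemispheres. For a point on the mirror plane the pair collapses to the
#' single 3-column matrix.
#'
#' @param lf m x channels x 3 array from [lead_field_grid()].
#' @param grid the matching `opm_source_grid`.
#' @param i point index.
#' @return channels x 6 matrix (channels x 3 on the mirror plane).
#' @export
pair_lead_field <- function(lf, grid, i) {
  j <- grid$pair_index[i]
  if (is.na(j)) abort("Point has no mirror partner in the grid.")
  Li <- lf[i, , ]
  if (j == i) return(Li)
  cbind(Li, lf[j, , ])
}
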