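# Analytic spherical-head forward model: sensor layout, source grid and
# closed-form lead field for a dipole in a homogeneous conducting sphere.

#' Quasi-uniform spherical EEG sensor array
#'
#' Places `n_channels` sensors on a sphere using the deterministic Fibonacci
#' (golden-angle) lattice, a standard quasi-uniform covering. The layout stands
#' in for an equidistant electrode cap whose physical coordinates are not
#' available; it is reproducible and approximately equidistant.
#'
#' @param n_channels number of electrodes (default 60).
#' @param radius scalp sphere radius in metres (default 0.09).
#' @param names optional channel labels; defaults to `"E001"`, `"E002"`, ...
#' @return An object of class `sensor_array` with fields `positions`
#'   (n x 3 matrix, metres), `names`, `radius` and `reference = "average"`.
#' @export
sensor_array <- function(n_channels = 60L, radius = 0.09, names = NULL) {
  assert_that(n_channels >= 4, "need at least 4 channels, got %d", n_channels)
  assert_that(radius > 0, "radius must be positive")
  i <- seq_len(n_channels) - 0.5
  phi <- pi * (1 + sqrt(5)) * i        # golden angle increments
  z <- 1 - 2 * i / n_channels
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  if (is.null(names)) names <- sprintf("E%03d", seq_len(n_channels))
  assert_that(!anyDuplicated(names), "channel names must be unique")
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, names = names, radius = radius,
                 reference = "average"),
            class = "sensor_array")
}

#' Regular cubic source grid clipped to a sphere
#'
#' Builds a cubic lattice with the given spacing (default 0.005 m, i.e. the
#' 0.5 cm resolution used throughout the source analysis), centred on the
#' origin and clipped to the strict interior of a sphere. Voxels are ordered
#' lexicographically by (x, y, z) so downstream filter and cluster identities
#' are reproducible.
#'
#' @param radius sphere radius in metres.
#' @param spacing lattice spacing in metres (default 0.005).
#' @param labels optional function `f(positions)` returning a character label
#'   per voxel (an atlas substitute); default assigns octant labels via
#'   [octant_labels()].
#' @return An object of class `source_grid` with fields `positions`
#'   (n x 3 matrix), `spacing` and `region_labels`.
#' @export
build_grid <- function(radius, spacing = 0.005, labels = octant_labels) {
  assert_that(spacing > 0, "spacing must be positive")
  assert_that(radius > 0, "radius must be positive")
  ax <- seq(-floor(radius / spacing), floor(radius / spacing)) * spacing
  g <- expand.grid(z = ax, y = ax, x = ax, KEEP.OUT.ATTRS = FALSE)
  pos <- as.matrix(g[, c("x", "y", "z")])
  pos <- pos[row_norms(pos) < radius, , drop = FALSE]
  assert_that(nrow(pos) > 0, "empty grid: no lattice point inside radius %g", radius)
  ord <- order(pos[, 1], pos[, 2], pos[, 3])
  pos <- pos[ord, , drop = FALSE]
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = pos, spacing = spacing,
                 region_labels = if (is.null(labels)) NULL else labels(pos)),
            class = "source_grid")
}

#' Geometric octant labels for grid voxels
#'
#' Synthetic stand-in for anatomical atlas labels: each voxel is labelled by
#' the sign pattern of its coordinates, e.g. `"oct_R_ant_sup"`. Voxels on a
#' coordinate plane take the positive side. Supplying a voxel-label table of
#' your own (one label per voxel) replaces these throughout.
#'
#' @param positions n x 3 matrix of voxel coordinates.
#' @return character vector of length n.
#' @export
octant_labels <- function(positions) {
  side <- function(v, neg, pos) ifelse(v < 0, neg, pos)
  paste("oct",
        side(positions[, 1], "L", "R"),
        side(positions[, 2], "post", "ant"),
        side(positions[, 3], "inf", "sup"),
        sep = "_")
}

# Closed-form surface potential of a current dipole inside a homogeneous
# conducting sphere (insulating exterior). With f = |r0|/R, u the cosine of
# the angle between source and electrode, s = sqrt(1 - 2fu + f^2),
# A = q . r0_hat and B = q . r_hat - u A, the potential is
#   V = (A S1 + B S2) / (4 pi sigma R^2)
# where S1 and S2 are closed-form sums of the Legendre expansion:
#   S1 = (2f(u - f)/s^3 + 1/s - 1) / f
#   S2 = 2/s^3 + ((f - u)/s + u) / (f (1 - u^2)).
# The S2 fraction is rationalised for |u| near 1 to avoid cancellation, and a
# short series expansion is used for sources within 1e-3 R of the centre.
sphere_potential <- function(elec, dipole_pos, q, radius, conductivity) {
  b <- sqrt(sum(dipole_pos^2))
  rhat <- elec / sqrt(sum(elec^2))
  f <- b / radius
  c0 <- 1 / (4 * pi * conductivity * radius^2)
  if (f < 1e-3) {
    ahat <- if (b > 0) dipole_pos / b else c(0, 0, 1)
    u <- sum(rhat * ahat)
    A <- sum(q * ahat)
    B <- sum(q * rhat) - u * A
    p2 <- (3 * u^2 - 1) / 2
    p3 <- (5 * u^3 - 3 * u) / 2
    s1 <- 3 * u + 5 * f * p2 + 7 * f^2 * p3
    s2 <- 3 + 2.5 * f * (3 * u) + (7 / 3) * f^2 * ((15 * u^2 - 3) / 2)
    return(c0 * (A * s1 + B * s2))
  }
  ahat <- dipole_pos / b
  u <- sum(rhat * ahat)
  A <- sum(q * ahat)
  B <- sum(q * rhat) - u * A
  s <- sqrt(1 - 2 * f * u + f^2)
  s1 <- (2 * f * (u - f) / s^3 + 1 / s - 1) / f
  g <- if (abs(u) <= 0.9) {
    ((f - u) / s + u) / (1 - u^2)
  } else {
    f * (f - 2 * u) / (s * ((f - u) - u * s))
  }
  s2 <- 2 / s^3 + g / f
  c0 * (A * s1 + B * s2)
}

#' Lead field of a homogeneous spherical head model
#'
#' Computes the average-referenced gain of unit dipoles at every grid voxel
#' onto every sensor, using the closed-form potential of a dipole inside a
#' homogeneous conducting sphere. Units: volts per ampere-metre.
#'
#' @param grid a [build_grid()] source grid; all voxels must lie strictly
#'   inside the sphere.
#' @param sensors a [sensor_array()]; positions are radially projected onto
#'   the sphere surface (they must already lie within 1% of it).
#' @param sphere list with `center` (default origin), `radius` (default the
#'   sensor radius) and `conductivity` in S/m (default 0.33).
#' @return An object of class `lead_field` with `gain` (channels x voxels x 3
#'   orientations), `grid` and `sensors`.
#' @export
spherical_leadfield <- function(grid, sensors,
                                sphere = list(center = c(0, 0, 0),
                                              radius = sensors$radius,
                                              conductivity = 0.33)) {
  center <- if (is.null(sphere$center)) c(0, 0, 0) else sphere$center
  radius <- if (is.null(sphere$radius)) sensors$radius else sphere$radius
  cond <- if (is.null(sphere$conductivity)) 0.33 else sphere$conductivity
  assert_that(radius > 0 && cond > 0, "sphere radius and conductivity must be positive")

  vox <- sweep(grid$positions, 2, center)
  assert_that(all(row_norms(vox) < radius * (1 - 1e-9)),
              "all source voxels must lie strictly inside the sphere (singularity on the surface)")
  sens <- sweep(sensors$positions, 2, center)
  sr <- row_norms(sens)
  assert_that(all(abs(sr - radius) < 0.01 * radius),
              "sensor positions must lie on the sphere surface")
  sens <- sens * (radius / sr)  # exact radial projection

  n_ch <- nrow(sens)
  n_vx <- nrow(vox)
  gain <- array(0, dim = c(n_ch, n_vx, 3),
                dimnames = list(sensors$names, NULL, c("qx", "qy", "qz")))
  rhat <- sens / radius
  c0 <- 1 / (4 * pi * cond * radius^2)
  for (v in seq_len(n_vx)) {
    b <- sqrt(sum(vox[v, ]^2))
    f <- b / radius
    ahat <- if (b > 0) vox[v, ] / b else c(0, 0, 1)
    u <- drop(rhat %*% ahat)                       # per-channel cos(angle)
    if (f < 1e-3) {
      p2 <- (3 * u^2 - 1) / 2
      p3 <- (5 * u^3 - 3 * u) / 2
      s1 <- 3 * u + 5 * f * p2 + 7 * f^2 * p3
      s2 <- 3 + 7.5 * f * u + (7 / 3) * f^2 * ((15 * u^2 - 3) / 2)
    } else {
      s <- sqrt(1 - 2 * f * u + f^2)
      s1 <- (2 * f * (u - f) / s^3 + 1 / s - 1) / f
      g <- ifelse(abs(u) <= 0.9,
                  ((f - u) / s + u) / (1 - u^2),
                  f * (f - 2 * u) / (s * ((f - u) - u * s)))
      s2 <- 2 / s^3 + g / f
    }
    # gain for unit dipoles along x, y, z: A_o = ahat[o], B_o = rhat - u ahat[o]
    for (o in 1:3) {
      gain[, v, o] <- c0 * (ahat[o] * s1 + (rhat[, o] - u * ahat[o]) * s2)
    }
  }
  # average reference: each gain column sums to zero over channels
  for (o in 1:3) {
    gain[, , o] <- sweep(gain[, , o, drop = FALSE][, , 1],
                         2, colMeans(gain[, , o, drop = FALSE][, , 1]))
  }
  structure(list(gain = gain, grid = grid, sensors = sensors,
                 sphere = list(center = center, radius = radius,
                               conductivity = cond)),
            class = "lead_field")
}

#' Lead-field matrix of one voxel
#'
#' @param lf a [spherical_leadfield()] object.
#' @param voxel voxel index.
#' @return channels x 3 gain matrix.
#' @export
leadfield_at <- function(lf, voxel) {
  assert_that(voxel >= 1 && voxel <= dim(lf$gain)[2], "voxel index out of range")
  lf$gain[, voxel, ]
}
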