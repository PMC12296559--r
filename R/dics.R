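# Frequency-domain source analysis: cross-spectral density, DICS common
# spatial filters, source power maps and the FR/FA power-ratio map.

#' Cross-spectral density matrix
#'
#' Per-trial Hanning-tapered FFT of the samples in the half-open window
#' `window_ms`; cross-spectra are averaged over the FFT bins falling in
#' `band` (inclusive) and over trials. The result is Hermitian with a real
#' non-negative diagonal.
#'
#' @param epochs an [epoch_set()].
#' @param band `c(low, high)` Hz or band name.
#' @param window_ms half-open analysis window (ms relative to S2); must span
#'   at least one cycle of the band's lowest frequency.
#' @param trials optional trial subset (indices or logical).
#' @return An object of class `csd_matrix`: `csd` (channels x channels,
#'   complex), `band`, `window_ms`, `taper = "hanning"`, `n_trials`,
#'   `channels`.
#' @export
csd <- function(epochs, band, window_ms, trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(band)) band <- BANDS[[match.arg(band, names(BANDS))]]
  times <- epoch_times(epochs)
  idx <- window_samples(times, window_ms)
  n_s <- length(idx)
  assert_that(n_s / epochs$sfreq >= 1 / band[1],
              "window too short: need at least one cycle of %g Hz", band[1])
  sel <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else
    seq_len(dim(epochs$data)[1])[trials]
  assert_that(length(sel) > 0, "no trials selected")
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, n_s - 1) / (n_s - 1)))  # Hanning
  freqs <- (seq_len(n_s) - 1) * epochs$sfreq / n_s
  bins <- which(freqs >= band[1] & freqs <= band[2])
  assert_that(length(bins) > 0, "no FFT bin inside band [%g, %g] Hz", band[1], band[2])
  n_ch <- dim(epochs$data)[2]
  acc <- matrix(0 + 0i, n_ch, n_ch)
  scale <- 1 / (sum(taper^2) * epochs$sfreq)   # periodogram normalisation
  for (tr in sel) {
    x <- matrix(epochs$data[tr, , idx], n_ch, n_s)
    x <- x - rowMeans(x)
    xt <- x * matrix(taper, n_ch, n_s, byrow = TRUE)
    X <- t(stats::mvfft(t(xt)))                # channels x freq bins
    for (b in bins) acc <- acc + (X[, b] %o% Conj(X[, b])) * scale
  }
  C <- acc / (length(sel) * length(bins))
  C <- (C + Conj(t(C))) / 2                    # enforce exact Hermitianity
  structure(list(csd = C, band = band, window_ms = window_ms,
                 taper = "hanning", n_trials = length(sel),
                 channels = epochs$channels),
            class = "csd_matrix")
}

regularized <- function(C, lambda) {
  C + lambda * mean(Re(diag(C))) * diag(nrow(C))
}

solve_checked <- function(M, what = "matrix") {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(Mod(out)))) {
    sv <- tryCatch(svd(M, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
    stop(sprintf("%s is singular or near-singular (condition number %.3g); increase lambda",
                 what, max(sv) / max(min(sv), .Machine$double.xmin)),
         call. = FALSE)
  }
  out
}

#' DICS spatial filters (common filter)
#'
#' Unit-gain scalar beamformer in the frequency domain. The CSD is
#' regularized as `C + lambda * mean(diag(C)) * I`; for every voxel the
#' dipole orientation maximizing output power is selected (the eigenvector of
#' the smallest eigenvalue of `Re(L' C^-1 L)`), then
#' `w = (l' C^-1 l)^-1 l' C^-1` with `l` the oriented lead field, so that
#' `w l = 1` by construction. Computed once from data pooled across all
#' conditions ("common filter") and applied per condition to avoid filter
#' bias.
#'
#' @param csd_common a [csd()] matrix pooled over all conditions.
#' @param leadfield a [spherical_leadfield()].
#' @param lambda regularization as a fraction of mean sensor power
#'   (default 0.05).
#' @param voxels optional voxel subset (default all).
#' @return An object of class `spatial_filters`: `weights` (voxels x
#'   channels, complex), `orientations` (voxels x 3), `voxels`, `lambda`,
#'   `band`, `noise_power` (per voxel, for the neural activity index).
#' @export
dics_filters <- function(csd_common, leadfield, lambda = 0.05, voxels = NULL) {
  stopifnot(inherits(csd_common, "csd_matrix"))
  assert_that(identical(csd_common$channels, dimnames(leadfield$gain)[[1]]),
              "CSD and lead field channel sets differ")
  if (is.null(voxels)) voxels <- seq_len(dim(leadfield$gain)[2])
  Cr <- regularized(csd_common$csd, lambda)
  Ci <- solve_checked(Cr, "regularized CSD")
  noise <- lambda * mean(Re(diag(csd_common$csd)))
  n_ch <- nrow(Cr)
  W <- matrix(0 + 0i, length(voxels), n_ch)
  ori <- matrix(0, length(voxels), 3)
  npow <- numeric(length(voxels))
  for (k in seq_along(voxels)) {
    L <- leadfield$gain[, voxels[k], ]            # channels x 3
    M <- Re(Conj(t(L)) %*% Ci %*% L)              # 3 x 3
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- eg$vectors[, 3]                          # min-eigenvalue direction
    l <- drop(L %*% u)
    denom <- drop(Re(Conj(l) %*% Ci %*% l))
    w <- drop(Conj(l) %*% Ci) / denom
    W[k, ] <- w
    ori[k, ] <- u
    npow[k] <- noise * sum(Mod(w)^2)
  }
  structure(list(weights = W, orientations = ori, voxels = voxels,
                 lambda = lambda, band = csd_common$band,
                 channels = csd_common$channels, noise_power = npow),
            class = "spatial_filters")
}

#' Source power map from spatial filters and a condition CSD
#'
#' `P_v = Re(w C w^H)` with the common filters and a condition-specific CSD.
#' With `kind = "nai"` the neural activity index `P_v / noise_power_v`
#' (unit-noise-gain normalization against the regularization noise floor) is
#' returned instead.
#'
#' @param filters [dics_filters()] output.
#' @param csd_condition a [csd()] matrix for one condition (same channels).
#' @param kind `"power"` (default) or `"nai"`.
#' @return An object of class `source_power_map`: `value` per voxel,
#'   `voxels`, `band`, `window_ms`, `kind`.
#' @export
source_power <- function(filters, csd_condition, kind = c("power", "nai")) {
  kind <- match.arg(kind)
  stopifnot(inherits(filters, "spatial_filters"),
            inherits(csd_condition, "csd_matrix"))
  assert_that(identical(filters$channels, csd_condition$channels),
              "filters and CSD have mismatched channels")
  C <- csd_condition$csd
  p <- vapply(seq_len(nrow(filters$weights)), function(k) {
    w <- filters$weights[k, ]
    Re(drop(w %*% C %*% Conj(w)))
  }, 0)
  if (kind == "nai") p <- p / filters$noise_power
  structure(list(value = p, voxels = filters$voxels, band = filters$band,
                 window_ms = csd_condition$window_ms, kind = kind),
            class = "source_power_map")
}

#' FR/FA source power-ratio map
#'
#' `ratio = (P_FR - P_FA) / (P_FR + P_FA)`, voxel-wise, in [-1, 1]; defined
#' as 0 where both powers are 0. Invariant to a common rescaling of both
#' maps.
#'
#' @param p_fr,p_fa [source_power_map()]s on the same voxels and band.
#' @return a `source_power_map` with `kind = "ratio"`.
#' @export
power_ratio <- function(p_fr, p_fa) {
  stopifnot(inherits(p_fr, "source_power_map"), inherits(p_fa, "source_power_map"))
  assert_that(identical(p_fr$voxels, p_fa$voxels) &&
                identical(p_fr$band, p_fa$band),
              "ratio requires maps on the same voxels and band")
  assert_that(all(p_fr$value >= 0) && all(p_fa$value >= 0),
              "power maps must be non-negative")
  denom <- p_fr$value + p_fa$value
  r <- ifelse(denom > 0, (p_fr$value - p_fa$value) / denom, 0)
  structure(list(value = r, voxels = p_fr$voxels, band = p_fr$band,
                 window_ms = p_fr$window_ms, kind = "ratio"),
            class = "source_power_map")
}

#' Export a source map as a table
#'
#' @param map a [source_power_map()].
#' @param grid the [build_grid()] the map lives on.
#' @return data.frame with `voxel`, `x`, `y`, `z`, `value`.
#' @export
source_map_table <- function(map, grid) {
  pos <- grid$positions[map$voxels, , drop = FALSE]
  data.frame(voxel = map$voxels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             value = map$value)
}
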