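# Time-domain LCMV beamforming: TOI covariance, unit-gain scalar filters,
# cluster time series and their wavelet band-power courses.

#' Channel covariance within a time interval of interest
#'
#' Pools the samples of the half-open TOI over trials after removing each
#' trial's per-channel mean within the TOI.
#'
#' @param epochs an [epoch_set()].
#' @param toi_ms half-open interval (ms relative to S2).
#' @param trials optional trial subset.
#' @return list of class `toi_covariance`: `cov` (channels x channels),
#'   `toi_ms`, `n_trials`, `channels`.
#' @export
toi_covariance <- function(epochs, toi_ms, trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_samples(epoch_times(epochs), toi_ms)
  assert_that(length(idx) >= 2, "TOI must contain at least 2 samples")
  sel <- if (is.null(trials)) seq_len(dim(epochs$data)[1]) else
    seq_len(dim(epochs$data)[1])[trials]
  n_ch <- dim(epochs$data)[2]
  acc <- matrix(0, n_ch, n_ch)
  for (tr in sel) {
    x <- matrix(epochs$data[tr, , idx], n_ch, length(idx))
    x <- x - rowMeans(x)
    acc <- acc + tcrossprod(x) / (length(idx) - 1)
  }
  structure(list(cov = acc / length(sel), toi_ms = toi_ms,
                 n_trials = length(sel), channels = epochs$channels),
            class = "toi_covariance")
}

#' LCMV spatial filters
#'
#' Same algebra as [dics_filters()] with a real covariance matrix: unit-gain
#' scalar beamformer with power-maximizing orientation per voxel, typically
#' restricted to the member voxels of a DBSCAN cluster (the imported source
#' model).
#'
#' @param cov a [toi_covariance()].
#' @param leadfield a [spherical_leadfield()].
#' @param voxels voxel indices to build filters for (default all).
#' @param lambda regularization fraction (default 0.05, shared with DICS).
#' @return a `spatial_filters` object (real weights).
#' @export
lcmv_filters <- function(cov, leadfield, voxels = NULL, lambda = 0.05) {
  stopifnot(inherits(cov, "toi_covariance"))
  assert_that(identical(cov$channels, dimnames(leadfield$gain)[[1]]),
              "covariance and lead field channel sets differ")
  if (is.null(voxels)) voxels <- seq_len(dim(leadfield$gain)[2])
  Cr <- regularized(cov$cov, lambda)
  Ci <- solve_checked(Cr, "regularized covariance")
  noise <- lambda * mean(diag(cov$cov))
  W <- matrix(0, length(voxels), nrow(Cr))
  ori <- matrix(0, length(voxels), 3)
  npow <- numeric(length(voxels))
  for (k in seq_along(voxels)) {
    L <- leadfield$gain[, voxels[k], ]
    M <- t(L) %*% Ci %*% L
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- eg$vectors[, 3]
    l <- drop(L %*% u)
    w <- drop(l %*% Ci) / drop(l %*% Ci %*% l)
    W[k, ] <- w
    ori[k, ] <- u
    npow[k] <- noise * sum(w^2)
  }
  structure(list(weights = W, orientations = ori, voxels = voxels,
                 lambda = lambda, band = NULL, channels = cov$channels,
                 noise_power = npow, toi_ms = cov$toi_ms),
            class = "spatial_filters")
}

#' Reconstructed cluster time series
#'
#' Applies the LCMV filters of the cluster's member voxels to every trial and
#' averages the reconstructed (raw, signed) voxel series within the cluster.
#'
#' @param filters [lcmv_filters()] built on (a superset of) the cluster
#'   voxels.
#' @param epochs an [epoch_set()].
#' @param cluster_voxels voxel indices (into the grid) forming the cluster.
#' @return trials x samples matrix of the cluster-mean source series, with
#'   the epoch time axis in `attr(, "times")`.
#' @export
cluster_timeseries <- function(filters, epochs, cluster_voxels) {
  stopifnot(inherits(filters, "spatial_filters"), inherits(epochs, "epoch_set"))
  assert_that(length(cluster_voxels) > 0, "empty cluster")
  rows <- match(cluster_voxels, filters$voxels)
  assert_that(!anyNA(rows), "cluster voxels missing from the filter set")
  d <- dim(epochs$data)
  out <- matrix(0, d[1], d[3])
  Wc <- filters$weights[rows, , drop = FALSE]
  for (tr in seq_len(d[1])) {
    x <- matrix(epochs$data[tr, , ], d[2], d[3])
    out[tr, ] <- colMeans(Re(Wc %*% x))
  }
  attr(out, "times") <- epoch_times(epochs)
  out
}

#' Band-power time course of a cluster series
#'
#' Morlet band power of the cluster-mean series, averaged over trials and
#' band frequencies, restricted to a TOI. This is the participant-level
#' quantity entering the pre/post correlation analysis.
#'
#' @param series trials x samples matrix from [cluster_timeseries()] (with
#'   its `times` attribute).
#' @param sfreq sampling rate (Hz).
#' @param band band name or `c(low, high)` Hz.
#' @param toi_ms half-open TOI; `NULL` keeps the whole epoch.
#' @param width wavelet width (default 5).
#' @param n_freqs analysis frequencies spread over the band (default 4).
#' @return named numeric vector: power per TOI sample (names = time in ms).
#' @export
cluster_band_course <- function(series, sfreq, band, toi_ms = NULL, width = 5,
                                n_freqs = 4L) {
  if (is.character(band)) band <- BANDS[[match.arg(band, names(BANDS))]]
  times <- attr(series, "times")
  assert_that(!is.null(times), "series must carry its 'times' attribute")
  freqs <- seq(band[1], band[2], length.out = n_freqs)
  wl <- lapply(freqs, morlet_wavelet, sfreq = sfreq, width = width)
  p <- matrix(0, nrow(series), ncol(series))
  for (tr in seq_len(nrow(series))) {
    for (w in wl) p[tr, ] <- p[tr, ] + Mod(fft_convolve_same(series[tr, ], w))^2
  }
  course <- colMeans(p) / length(wl)
  names(course) <- times
  if (!is.null(toi_ms)) {
    idx <- window_samples(times, toi_ms)
    assert_that(length(idx) > 0, "TOI outside the epoch")
    course <- course[idx]
  }
  course
}

#' FR - FA interaction course
#'
#' Element-wise difference of matched FR and FA cluster band-power courses
#' (participants x times), the time-resolved binding signature of a
#' post-trial cluster.
#'
#' @param cts_fr,cts_fa numeric matrices participants x times with identical
#'   dimensions (and dimnames, if set).
#' @return matrix of the same shape.
#' @export
interaction_course <- function(cts_fr, cts_fa) {
  assert_that(identical(dim(cts_fr), dim(cts_fa)),
              "FR and FA courses must be participant/time matched")
  if (!is.null(dimnames(cts_fr)) && !is.null(dimnames(cts_fa))) {
    assert_that(identical(dimnames(cts_fr), dimnames(cts_fa)),
                "FR and FA courses must be participant/time matched")
  }
  cts_fr - cts_fa
}
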