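# Morlet wavelet time-frequency analysis and sensor-level FR-vs-FA contrasts
# with Benjamini-Hochberg FDR control.

#' Complex Morlet wavelet
#'
#' Gaussian-windowed complex exponential with `width` cycles within one
#' temporal SD times 2pi (the usual "number of cycles" convention:
#' `sigma_t = width / (2 pi f)`), normalized to unit total energy so the
#' expected power of white noise is flat across frequencies.
#' @noRd
morlet_wavelet <- function(freq, sfreq, width = 5) {
  sigma_t <- width / (2 * pi * freq)
  half <- ceiling(5 * sigma_t * sfreq)
  t <- (-half:half) / sfreq
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w / sqrt(sum(Mod(w)^2))
}

fft_convolve_same <- function(x, k) {
  # linear convolution, central part of length(x)
  n <- length(x) + length(k) - 1L
  nf <- stats::nextn(n, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, nf - length(x)))) *
                  stats::fft(c(k, rep(0, nf - length(k)))), inverse = TRUE) / nf
  start <- (length(k) - 1L) %/% 2L + 1L
  y[start:(start + length(x) - 1L)]
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with unit-energy complex Morlet wavelets
#' and returns squared magnitude (power, uV^2). Samples closer to an epoch
#' edge than half the wavelet support are flagged invalid in the `valid`
#' matrix (freqs x times) since their estimates mix in zero padding.
#'
#' @param epochs an [epoch_set()].
#' @param freqs numeric vector of analysis frequencies (Hz), strictly
#'   positive, below Nyquist.
#' @param width wavelet width in cycles (default 5).
#' @param average average power across trials (default `FALSE`).
#' @return An object of class `tfr_result`: `power` (trials-or-1 x channels x
#'   freqs x times), `freqs`, `times` (ms relative to S2), `sfreq`, `width`,
#'   `valid`, plus the epoch metadata.
#' @export
morlet_tfr <- function(epochs, freqs, width = 5, average = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  assert_that(all(freqs > 0), "frequencies must be positive")
  assert_that(all(freqs < epochs$sfreq / 2), "frequencies must be below Nyquist")
  assert_that(!is.unsorted(freqs, strictly = TRUE), "freqs must be strictly increasing")
  d <- dim(epochs$data)
  n_t <- d[3]
  times <- epoch_times(epochs)
  wavelets <- lapply(freqs, morlet_wavelet, sfreq = epochs$sfreq, width = width)
  half_support <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, 0L)
  assert_that(max(vapply(wavelets, length, 0L)) <= n_t,
              "epoch too short for the lowest-frequency wavelet")
  valid <- matrix(TRUE, length(freqs), n_t)
  for (fi in seq_along(freqs)) {
    h <- half_support[fi]
    if (h > 0) valid[fi, c(seq_len(h), (n_t - h + 1L):n_t)] <- FALSE
  }
  n_out_tr <- if (average) 1L else d[1]
  power <- array(0, dim = c(n_out_tr, d[2], length(freqs), n_t))
  # batched FFT convolution: one forward transform per trial, reused for all
  # frequencies; one inverse transform per (trial, frequency)
  max_k <- max(vapply(wavelets, length, 0L))
  nf <- stats::nextn(n_t + max_k - 1L, 2)
  Wf <- lapply(wavelets, function(w) stats::fft(c(w, rep(0, nf - length(w)))))
  for (tr in seq_len(d[1])) {
    dest <- if (average) 1L else tr
    xm <- rbind(t(matrix(epochs$data[tr, , ], d[2], n_t)),
                matrix(0, nf - n_t, d[2]))
    X <- stats::mvfft(xm)
    for (fi in seq_along(freqs)) {
      Y <- stats::mvfft(X * Wf[[fi]], inverse = TRUE) / nf
      start <- half_support[fi] + 1L
      p <- Mod(Y[start:(start + n_t - 1L), , drop = FALSE])^2
      power[dest, , fi, ] <- power[dest, , fi, ] + t(p)
    }
  }
  if (average) power <- power / d[1]
  structure(list(power = power, freqs = freqs, times = times,
                 sfreq = epochs$sfreq, width = width, valid = valid,
                 channels = epochs$channels,
                 conditions = if (average) NULL else epochs$conditions,
                 participant = epochs$participant, group = epochs$group),
            class = "tfr_result")
}

#' Band- and window-averaged power
#'
#' Mean power over the analysis frequencies falling in `band` (inclusive) and
#' the samples in the half-open window `window_ms`.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param band numeric `c(low, high)` in Hz, or a band name
#'   (`"theta"`, `"alpha"`, `"beta"`).
#' @param window_ms half-open time window in ms relative to S2.
#' @return trials x channels matrix of mean power.
#' @export
band_power <- function(tfr, band, window_ms) {
  stopifnot(inherits(tfr, "tfr_result"))
  if (is.character(band)) band <- BANDS[[match.arg(band, names(BANDS))]]
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  assert_that(length(fi) > 0, "no analysis frequency inside band [%g, %g] Hz",
              band[1], band[2])
  ti <- window_samples(tfr$times, window_ms)
  assert_that(length(ti) > 0 &&
                window_ms[1] >= tfr$times[1] &&
                window_ms[2] <= tfr$times[length(tfr$times)] + 1000 / tfr$sfreq,
              "window [%g, %g] ms outside the epoch", window_ms[1], window_ms[2])
  out <- apply(tfr$power[, , fi, ti, drop = FALSE], c(1, 2), mean)
  dimnames(out) <- list(NULL, tfr$channels)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-missing members of a p-value family;
#' `NA` entries are excluded from the family and returned as `NA`.
#'
#' @param p numeric vector of p-values (may contain `NA`).
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-channel, per-time-bin FR vs FA paired t tests
#'
#' Compares band power between feature repetition and feature alternation
#' within a response-relation condition, per channel and time bin, across
#' participants (paired). P-values are BH-adjusted across the channels x bins
#' family; significance is declared at adjusted p < `alpha`. Channels/bins
#' with degenerate difference variance are excluded from the family.
#'
#' @param power_fr,power_fa numeric arrays participants x channels x bins
#'   (bins may be 1) of band power for the FR and FA conditions.
#' @param bin_windows optional list of `c(start, end)` ms labels per bin.
#' @param channels optional channel names.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame with columns `channel`, `bin`, `t`, `p`, `p_adj`,
#'   `significant` (class `sensor_contrast`).
#' @export
fr_vs_fa_ttests <- function(power_fr, power_fa, bin_windows = NULL,
                            channels = NULL, alpha = 0.05) {
  if (length(dim(power_fr)) == 2L) {
    power_fr <- array(power_fr, dim = c(dim(power_fr), 1L))
    power_fa <- array(power_fa, dim = c(dim(power_fa), 1L))
  }
  assert_that(identical(dim(power_fr), dim(power_fa)),
              "FR and FA arrays must have identical dimensions")
  d <- dim(power_fr)
  assert_that(d[1] >= 2, "need at least 2 participants")
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(d[2]))
  diff <- power_fr - power_fa
  rows <- expand.grid(channel = seq_len(d[2]), bin = seq_len(d[3]))
  t_stat <- p <- rep(NA_real_, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    x <- diff[, rows$channel[i], rows$bin[i]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) next  # degenerate: excluded from family
    t_stat[i] <- mean(x) / (s / sqrt(d[1]))
    p[i] <- 2 * stats::pt(-abs(t_stat[i]), d[1] - 1)
  }
  p_adj <- bh_adjust(p)
  out <- data.frame(channel = channels[rows$channel], bin = rows$bin,
                    t = t_stat, p = p, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha)
  if (!is.null(bin_windows)) {
    out$bin_start <- vapply(bin_windows, `[`, 0, 1)[out$bin]
    out$bin_end <- vapply(bin_windows, `[`, 0, 2)[out$bin]
  }
  class(out) <- c("sensor_contrast", "data.frame")
  out
}

#' Band power per time bin for the sensor contrast
#'
#' Splits `window_ms` into consecutive `bin_ms` bins (half-open) and averages
#' band power within each, returning participants-ready channel x bin values
#' for one epoch set (trials are averaged).
#'
#' @param tfr a [morlet_tfr()] result (single participant, per-trial power).
#' @param band band name or `c(low, high)` Hz.
#' @param window_ms analysis window, default `c(0, 1000)`.
#' @param bin_ms bin width in ms, default 50.
#' @param trials optional logical/integer trial subset (e.g. one condition).
#' @return channels x bins matrix; bin windows in `attr(, "bins")`.
#' @export
band_power_bins <- function(tfr, band, window_ms = c(0, 1000), bin_ms = 50,
                            trials = NULL) {
  starts <- seq(window_ms[1], window_ms[2] - bin_ms, by = bin_ms)
  bins <- lapply(starts, function(s) c(s, s + bin_ms))
  sel_power <- if (is.null(trials)) tfr$power else tfr$power[trials, , , , drop = FALSE]
  tfr_sub <- tfr
  tfr_sub$power <- sel_power
  out <- vapply(bins, function(b) colMeans(band_power(tfr_sub, band, b)),
                numeric(dim(sel_power)[2]))
  attr(out, "bins") <- bins
  out
}
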