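# Self-contained validation experiments: parameter-recovery simulations,
# oracle equivalences and null calibrations. Shared by the test suite and by
# scripts/acceptance.R.

#' DICS dipole-localization recovery rate
#'
#' Repeatedly simulates a single oscillating dipole at a random grid voxel,
#' with white sensor noise scaled so the mean sensor-level signal-to-noise
#' variance ratio equals `snr`, runs the full CSD -> common-filter -> source
#' power chain, and scores a hit when the power maximum lies within one grid
#' step of the true voxel.
#'
#' @param n_seeds number of independent simulations (default 100).
#' @param snr sensor-level variance SNR (default 10).
#' @param seed base RNG seed.
#' @param n_channels,grid_radius,spacing head-model size.
#' @param trials_per_condition trials per condition per simulation.
#' @return list with `hit_rate_pct`, `n_seeds`.
#' @export
dics_localization_check <- function(n_seeds = 100, snr = 10, seed = 1L,
                                    n_channels = 24, grid_radius = 0.05,
                                    spacing = 0.0125,
                                    trials_per_condition = 3L) {
  sensors <- sensor_array(n_channels)
  grid <- build_grid(grid_radius, spacing)
  lf <- spherical_leadfield(grid, sensors)
  n_vox <- nrow(grid$positions)
  amp <- 60
  hits <- 0L
  for (k in seq_len(n_seeds)) {
    sk <- (seed * 131L + k) %% 2147483647L
    vox <- with_seed(sk, sample.int(n_vox, 1))
    ori <- default_orientation(grid$positions[vox, ])
    g <- drop(lf$gain[, vox, ] %*% ori)
    sig_var <- mean((g * amp * 1e-3)^2) / 2      # sine variance per channel
    noise_sd <- sqrt(sig_var / snr)
    p <- eeg_sim_params(
      list(list(voxel = vox, freq = 10, orientation = ori,
                amplitude = matrix(c(0, 0, amp), 4, 3, byrow = TRUE,
                                   dimnames = list(CONDITIONS,
                                                   names(PERIODS))))),
      noise_sd = noise_sd, epoch_ms = c(-1000, 1500),
      trials_per_condition = trials_per_condition, seed = sk)
    ep <- generate_eeg(p, lf)
    cs <- csd(ep, c(8, 12), c(0, 1000))
    fl <- dics_filters(cs, lf, lambda = 0.05)
    pm <- source_power(fl, cs)
    est <- which.max(pm$value)
    d <- sqrt(sum((grid$positions[est, ] - grid$positions[vox, ])^2))
    if (d <= spacing * 1.01) hits <- hits + 1L
  }
  list(hit_rate_pct = 100 * hits / n_seeds, n_seeds = n_seeds)
}

#' Recovery of a planted pre/post amplitude coupling
#'
#' Simulates one participant with `n_units` trials, a pre-trial source active
#' in the post-S1 window and a post-trial source active in the post-S2
#' window, their per-trial amplitudes coupled at `rho`. Both sources are
#' reconstructed with LCMV, per-trial wavelet band power is evaluated at a
#' decimated set of time points in each window, and [timewise_correlation()]
#' is computed with trials as the observational units. Returns the mean
#' correlation over the matrix and its Fisher 95% CI at `n_units`.
#'
#' @param rho planted coupling (default 0.7).
#' @param n_units number of trials (default 200).
#' @param seed RNG seed.
#' @return list with `r_hat`, `ci` (95% CI around `r_hat`), `rho`, `n`.
#' @export
coupling_recovery_check <- function(rho = 0.7, n_units = 200, seed = 1L) {
  sensors <- sensor_array(24)
  grid <- build_grid(0.05, 0.0125)
  lf <- spherical_leadfield(grid, sensors)
  v1 <- 40
  v2 <- 200
  p <- eeg_sim_params(
    list(list(voxel = v1, freq = 6,
              amplitude = matrix(c(60, 0, 0), 4, 3, byrow = TRUE,
                                 dimnames = list(CONDITIONS, names(PERIODS)))),
         list(voxel = v2, freq = 6,
              amplitude = matrix(c(0, 0, 60), 4, 3, byrow = TRUE,
                                 dimnames = list(CONDITIONS, names(PERIODS))))),
    coupling = list(pre_source = 1, pre_period = "post_s1",
                    post_source = 2, post_period = "post_s2", rho = rho),
    noise_sd = 0.05, trials_per_condition = ceiling(n_units / 4),
    seed = seed)
  ep <- generate_eeg(p, lf)

  # per-trial band power in four 250 ms sub-windows of the TOI; wavelet
  # frequencies within one bandwidth of the planted 6 Hz source
  trial_courses <- function(vox, toi) {
    cv <- toi_covariance(ep, toi)
    fl <- lcmv_filters(cv, lf, voxels = vox, lambda = 0.05)
    ser <- cluster_timeseries(fl, ep, vox)
    times <- attr(ser, "times")
    idx <- window_samples(times, toi)
    bins <- split(idx, cut(seq_along(idx), 4))
    freqs <- seq(5, 7, length.out = 3)
    out <- matrix(0, nrow(ser), length(bins))
    for (tr in seq_len(nrow(ser))) {
      pw <- numeric(length(times))
      for (f in freqs) {
        w <- morlet_wavelet(f, ep$sfreq, 5)
        pw <- pw + Mod(fft_convolve_same(ser[tr, ], w))^2
      }
      out[tr, ] <- vapply(bins, function(b) mean(pw[b]), 0) / length(freqs)
    }
    out
  }
  pre <- trial_courses(v1, c(-2500, -1500))
  post <- trial_courses(v2, c(0, 1000))
  cm <- timewise_correlation(pre, post)
  r_hat <- mean(cm$r)
  n <- nrow(pre)
  ci <- tanh(atanh(r_hat) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  list(r_hat = r_hat, ci = ci, rho = rho, n = n)
}

#' Null calibration of the timewise correlation analysis
#'
#' Under independence (no planted coupling), power-like pre and post series
#' should yield about `alpha` raw-p false positives per matrix, and the BH
#' q-value mask should stay controlled at its level.
#'
#' @param n_rep replicates (default 200).
#' @param n_units observational units per replicate (default 30).
#' @param n_times time points per series (default 5).
#' @param alpha nominal level (default 0.05).
#' @param seed RNG seed.
#' @return list with `raw_fpr` (mean fraction of p < alpha cells),
#'   `fdr_rate` (mean fraction of q < alpha cells), `n_rep`.
#' @export
null_calibration_check <- function(n_rep = 200, n_units = 30, n_times = 5,
                                   alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    raw <- fdr <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      pre <- matrix(stats::rnorm(n_units * n_times)^2, n_units)
      post <- matrix(stats::rnorm(n_units * n_times)^2, n_units)
      cm <- timewise_correlation(pre, post)
      raw[i] <- mean(cm$p < alpha)
      fdr[i] <- mean(fdr_threshold(cm, alpha))
    }
    list(raw_fpr = mean(raw), fdr_rate = mean(fdr), n_rep = n_rep)
  })
}

#' DBSCAN vs eps-graph connected-components oracle
#'
#' @param n_sets random point sets (default 50).
#' @param seed RNG seed.
#' @return list with `agreement_pct`, `n_sets`.
#' @export
dbscan_oracle_check <- function(n_sets = 50, seed = 1L) {
  with_seed(seed, {
    agree <- vapply(seq_len(n_sets), function(i) {
      pts <- matrix(stats::runif(3 * sample(20:100, 1)), ncol = 3)
      eps <- stats::runif(1, 0.05, 0.3)
      identical_partition(dbscan_cluster(pts, eps = eps)$assignment,
                          eps_components_reference(pts, eps))
    }, TRUE)
    list(agreement_pct = 100 * mean(agree), n_sets = n_sets)
  })
}

#' BH adjustment vs brute-force step-up oracle
#'
#' @param n_draws random p-vectors (default 1000).
#' @param seed RNG seed.
#' @return list with `max_abs_diff`, `n_draws`.
#' @export
bh_oracle_check <- function(n_draws = 1000, seed = 1L) {
  with_seed(seed, {
    d <- vapply(seq_len(n_draws), function(i) {
      p <- stats::runif(sample(2:50, 1))
      max(abs(bh_adjust(p) - bh_stepup_reference(p)))
    }, 0)
    list(max_abs_diff = max(d), n_draws = n_draws)
  })
}

#' Mixed-ANOVA sums of squares vs a hand-computed toy decomposition
#'
#' Four participants (two per group) with integer cell means chosen so every
#' sum of squares can be computed by hand: the group SS is 9, the response
#' main/interaction/error SS are 4, 36 and 8, and the response x feature
#' contrast vanishes for every participant.
#'
#' @return list with `max_abs_diff` between computed and hand values.
#' @export
anova_toy_check <- function() {
  y <- rbind(c(10, 8, 6, 4), c(12, 10, 8, 6), c(9, 9, 9, 9), c(7, 9, 11, 13))
  cells <- data.frame(
    participant = rep(sprintf("s%d", 1:4), each = 4),
    group = rep(c("A", "A", "B", "B"), each = 4),
    response = rep(c("RR", "RR", "RA", "RA"), 4),
    feature = rep(c("FR", "FA", "FR", "FA"), 4),
    value = as.vector(t(y)))
  res <- mixed_anova_2x2x2(cells)
  ss <- attr(res, "ss")
  got <- c(ss$mean$between, ss$R$main, ss$R$between, ss$R$err, ss$RF$main)
  hand <- c(9, 4, 36, 8, 0)
  list(max_abs_diff = max(abs(got - hand)), n_terms = length(hand))
}
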