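test_that("TOI covariance has the expected structure", {
  set.seed(30)
  ep <- epoch_set(array(rnorm(40 * 4 * 512, 0, 2), c(40, 4, 512)), 256, 0,
                  c("a", "b", "c", "d"))
  ep$data[, 2, ] <- ep$data[, 1, ]   # duplicated channel
  cv <- toi_covariance(ep, c(200, 1800))
  expect_equal(cv$cov[1, 1], 4, tolerance = 0.2)
  expect_equal(cv$cov[1, 2] / sqrt(cv$cov[1, 1] * cv$cov[2, 2]), 1,
               tolerance = 1e-12)
  expect_lt(abs(cv$cov[3, 4]) / sqrt(cv$cov[3, 3] * cv$cov[4, 4]), 0.05)
  expect_error(toi_covariance(ep, c(0, 3)), "2 samples")
})

test_that("single-source covariance has rank 1 plus the noise floor", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 40, freq = 10,
                                amplitude = amp_matrix(0, list(period = "post_s2", amp = 50)))),
                      noise_sd = 0.2, trials_per_condition = 5, seed = 31)
  ep <- generate_eeg(p, lf)
  cv <- toi_covariance(ep, c(0, 1000))
  ev <- eigen(cv$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / ev[2], 50)                       # dominant source axis
  expect_equal(median(ev[-1]), 0.04, tolerance = 0.3)  # sigma^2 floor
})

test_that("LCMV filters have unit gain and recover the source time course", {
  lf <- fix_leadfield()
  grid <- fix_grid()
  vox <- 40
  p <- eeg_sim_params(list(list(voxel = vox, freq = 10,
                                amplitude = amp_matrix(0, list(period = "post_s2", amp = 60)))),
                      noise_sd = 0.5, amp_cv = 0, trials_per_condition = 5,
                      seed = 32)
  ep <- generate_eeg(p, lf)
  cv <- toi_covariance(ep, c(0, 1000))
  fl <- lcmv_filters(cv, lf, voxels = c(vox, 41), lambda = 0.05)
  for (k in 1:2) {
    l <- lf$gain[, fl$voxels[k], ] %*% fl$orientations[k, ]
    expect_lt(abs(drop(fl$weights[k, ] %*% l) - 1), 1e-8)
  }
  # reconstruction correlates > 0.95 with the true source inside its period
  ser <- cluster_timeseries(fl, ep, vox)
  times <- attr(ser, "times")
  idx <- which(times >= 0 & times < 1000)
  # rebuild the true oscillation from the projected sensor signal at high SNR:
  # use the noiseless trial signal correlation instead
  p0 <- p; p0$noise_sd <- 0
  ep0 <- generate_eeg(p0, lf)
  truth <- cluster_timeseries(lcmv_filters(toi_covariance(ep0, c(0, 1000)),
                                           lf, voxels = vox, lambda = 0.05),
                              ep0, vox)
  for (tr in 1:3) {
    expect_gt(abs(cor(ser[tr, idx], truth[tr, idx])), 0.95)
  }
})

test_that("identity covariance gives the minimum-norm limit", {
  lf <- fix_leadfield()
  cv <- structure(list(cov = diag(24), toi_ms = c(0, 1000), n_trials = 1,
                       channels = lf$sensors$names),
                  class = "toi_covariance")
  fl <- lcmv_filters(cv, lf, voxels = 25, lambda = 0)
  l <- drop(lf$gain[, 25, ] %*% fl$orientations[1, ])
  w <- fl$weights[1, ]
  expect_equal(w / sqrt(sum(w^2)), unname(sign(sum(w * l)) * l / sqrt(sum(l^2))),
               tolerance = 1e-10)
})

test_that("cluster series averaging behaves as stated", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 12, freq = 6,
                                amplitude = amp_matrix(0, list(period = "pre_s2", amp = 50)))),
                      trials_per_condition = 2, seed = 33)
  ep <- generate_eeg(p, lf)
  cv <- toi_covariance(ep, c(-1000, 0))
  fl <- lcmv_filters(cv, lf, voxels = c(12, 13), lambda = 0.05)
  one <- cluster_timeseries(fl, ep, 12)
  dup <- cluster_timeseries(fl, ep, c(12, 12))
  expect_equal(dup, one)
  two <- cluster_timeseries(fl, ep, c(12, 13))
  other <- cluster_timeseries(fl, ep, 13)
  expect_equal(two[1, ], (one[1, ] + other[1, ]) / 2)
  expect_error(cluster_timeseries(fl, ep, integer(0)), "empty cluster")
  expect_error(cluster_timeseries(fl, ep, 99), "missing from the filter set")
})

test_that("theta band course peaks inside the source's active period", {
  lf <- fix_leadfield()
  vox <- 40
  p <- eeg_sim_params(list(list(voxel = vox, freq = 6,
                                amplitude = amp_matrix(0, list(period = "pre_s2", amp = 60)))),
                      noise_sd = 0.5, trials_per_condition = 6, seed = 34)
  ep <- generate_eeg(p, lf)
  cv <- toi_covariance(ep, c(-1000, 0))
  fl <- lcmv_filters(cv, lf, voxels = vox, lambda = 0.05)
  ser <- cluster_timeseries(fl, ep, vox)
  course <- cluster_band_course(ser, ep$sfreq, "theta")
  t_ms <- as.numeric(names(course))
  peak <- t_ms[which.max(course)]
  expect_gte(peak, -1000)
  expect_lt(peak, 0)
  inside <- mean(course[t_ms >= -1000 & t_ms < 0])
  outside <- mean(course[t_ms >= -4000 & t_ms < -3000])
  expect_gt(inside / outside, 10)
})

test_that("interaction course is the element-wise FR - FA difference", {
  fr <- matrix(rnorm(20), 4)
  expect_equal(interaction_course(fr, fr), fr * 0)
  expect_equal(interaction_course(fr + 3, fr), matrix(3, 4, 5))
  expect_error(interaction_course(fr, fr[, 1:3]), "matched")
})

test_that("LCMV filters match DICS filters on a matched covariance", {
  lf <- fix_leadfield()
  set.seed(35)
  ep <- epoch_set(array(rnorm(30 * 24 * 512), c(30, 24, 512)), 256, 0,
                  lf$sensors$names)
  cv <- toi_covariance(ep, c(200, 1800))
  # feed the DICS routine the same (real) matrix as a CSD
  cs <- structure(list(csd = cv$cov + 0i, band = c(8, 12),
                       window_ms = c(200, 1800), taper = "hanning",
                       n_trials = 30, channels = lf$sensors$names),
                  class = "csd_matrix")
  fl_l <- lcmv_filters(cv, lf, voxels = 1:20, lambda = 0.05)
  fl_d <- dics_filters(cs, lf, lambda = 0.05, voxels = 1:20)
  for (k in c(1, 7, 20)) {
    wl <- fl_l$weights[k, ]
    wd <- Re(fl_d$weights[k, ])
    expect_lt(max(Mod(Im(fl_d$weights[k, ]))), 1e-12)
    # orientation sign is arbitrary; compare up to sign
    expect_lt(min(max(abs(wl - wd)), max(abs(wl + wd))), 1e-8 * max(abs(wl)))
  }
})
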