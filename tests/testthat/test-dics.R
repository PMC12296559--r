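noise_epochs <- function(n_trials, n_ch, n_s = 512, sfreq = 256, sd = 1,
                         seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_ch * n_s, 0, sd),
                  c(n_trials, n_ch, n_s)),
            sfreq, 0, sprintf("c%02d", seq_len(n_ch)))
}

test_that("CSD is Hermitian with expected structure", {
  ep <- noise_epochs(30, 4, seed = 2)
  # duplicate channel 2 into channel 1
  ep$data[, 1, ] <- ep$data[, 2, ]
  cs <- csd(ep, c(8, 12), c(500, 1500))
  C <- cs$csd
  expect_lt(max(Mod(C - Conj(t(C)))), 1e-10)
  expect_true(all(Re(diag(C)) >= 0))
  expect_equal(C[1, ], C[2, ], tolerance = 1e-12)
  coh <- Mod(C[1, 2]) / sqrt(Re(C[1, 1]) * Re(C[2, 2]))
  expect_equal(coh, 1, tolerance = 1e-12)
  expect_error(csd(ep, c(1, 2), c(500, 1000)), "window too short")
})

test_that("independent white-noise channels have vanishing cross-spectra", {
  ep <- noise_epochs(400, 2, seed = 3)
  cs <- csd(ep, c(8, 12), c(0, 2000))
  off <- cs$csd[1, 2]
  # SE of the mean cross-spectrum ~ power / sqrt(n_trials * n_bins)
  n_eff <- 400 * sum((0:511) * 0.5 >= 8 & (0:511) * 0.5 <= 12)
  se <- Re(cs$csd[1, 1]) / sqrt(n_eff)
  expect_lt(Mod(off), 3 * se)
})

test_that("a single projected source gives a rank-1 CSD in its band", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 40, freq = 10,
                                amplitude = amp_matrix(0, list(period = "post_s2", amp = 50)))),
                      noise_sd = 0, trials_per_condition = 3, seed = 4)
  ep <- generate_eeg(p, lf)
  cs <- csd(ep, c(8, 12), c(0, 1000))
  ev <- eigen(cs$csd, only.values = TRUE)$values
  expect_lt(Mod(ev[2]) / Mod(ev[1]), 1e-10)
})

test_that("DICS filters satisfy unit gain and the minimum-norm limit", {
  lf <- fix_leadfield()
  ep <- noise_epochs(20, 24, seed = 5)
  ep$channels <- lf$sensors$names
  cs <- csd(ep, c(8, 12), c(500, 1500))
  fl <- dics_filters(cs, lf, lambda = 0.05)
  # w . l = 1 for every voxel (oriented lead field)
  dev <- vapply(seq_len(nrow(fl$weights)), function(k) {
    l <- lf$gain[, fl$voxels[k], ] %*% fl$orientations[k, ]
    Mod(drop(fl$weights[k, ] %*% l) - 1)
  }, 0)
  expect_lt(max(dev), 1e-8)

  # identity CSD: w proportional to the oriented lead field
  cs_id <- cs
  cs_id$csd <- diag(24) + 0i
  fl_id <- dics_filters(cs_id, lf, lambda = 0)
  k <- 17
  l <- drop(lf$gain[, fl_id$voxels[k], ] %*% fl_id$orientations[k, ])
  w <- Re(fl_id$weights[k, ])
  expect_equal(w / sqrt(sum(w^2)), unname(sign(sum(w * l)) * l / sqrt(sum(l^2))),
               tolerance = 1e-8)
})

test_that("source power identities hold", {
  lf <- fix_leadfield()
  ep <- noise_epochs(20, 24, seed = 6)
  ep$channels <- lf$sensors$names
  cs <- csd(ep, c(8, 12), c(500, 1500))
  fl <- dics_filters(cs, lf, lambda = 0.05)
  p1 <- source_power(fl, cs)
  expect_true(all(p1$value >= 0))
  # P_v = (l' Cr^-1 l)^-1 when the condition CSD equals the common CSD
  Cr <- eegbind:::regularized(cs$csd, 0.05)
  Ci <- solve(Cr)
  k <- 10
  l <- drop(lf$gain[, fl$voxels[k], ] %*% fl$orientations[k, ])
  # w Cr w^H = (l' Cr^-1 l)^-1, so with C = Cr - lambda mu I:
  expect_equal(p1$value[k],
               Re(1 / drop(Conj(l) %*% Ci %*% l)) -
                 fl$lambda * mean(Re(diag(cs$csd))) * sum(Mod(fl$weights[k, ])^2),
               tolerance = 1e-6 * p1$value[k])
  # scaling the CSD scales all powers
  cs2 <- cs
  cs2$csd <- 3.7 * cs$csd
  p2 <- source_power(fl, cs2)
  expect_equal(p2$value, 3.7 * p1$value, tolerance = 1e-12)
})

test_that("DICS localizes two simultaneous equal-strength dipoles", {
  lf <- fix_leadfield()
  grid <- fix_grid()
  v1 <- 40
  d <- sqrt(rowSums(sweep(grid$positions, 2, grid$positions[v1, ])^2))
  v2 <- which(d > 0.045)[1]  # well-separated second source
  p <- eeg_sim_params(list(
    list(voxel = v1, freq = 10, amplitude = amp_matrix(0, list(period = "post_s2", amp = 50))),
    list(voxel = v2, freq = 10, amplitude = amp_matrix(0, list(period = "post_s2", amp = 50)))),
    noise_sd = 0.5, trials_per_condition = 10, seed = 7)
  ep <- generate_eeg(p, lf)
  cs <- csd(ep, c(8, 12), c(0, 1000))
  fl <- dics_filters(cs, lf, lambda = 0.05)
  pm <- source_power(fl, cs)
  top <- order(pm$value, decreasing = TRUE)
  near <- function(vox, set) {
    min(sqrt(rowSums(sweep(grid$positions[set, , drop = FALSE], 2,
                           grid$positions[vox, ])^2)))
  }
  expect_lte(near(v1, top[1:10]), grid$spacing * 1.01)
  expect_lte(near(v2, top[1:10]), grid$spacing * 1.01)
})

test_that("power ratio has the stated algebra and invariances", {
  mk <- function(v) structure(list(value = v, voxels = seq_along(v),
                                   band = c(8, 12), window_ms = c(0, 1000),
                                   kind = "power"),
                              class = "source_power_map")
  expect_equal(power_ratio(mk(c(1, 2, 0)), mk(c(1, 2, 0)))$value, c(0, 0, 0))
  expect_equal(power_ratio(mk(c(2, 1)), mk(c(0, 1)))$value, c(1, 0))
  expect_equal(power_ratio(mk(2), mk(1))$value, 1 / 3)
  # rescale invariance
  a <- mk(runif(5)); b <- mk(runif(5))
  a2 <- mk(a$value * 100); b2 <- mk(b$value * 100)
  expect_equal(power_ratio(a, b)$value, power_ratio(a2, b2)$value)
  expect_error(power_ratio(mk(c(-1, 1)), mk(c(1, 1))), "non-negative")
})
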