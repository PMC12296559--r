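test_that("behavioral simulator plants the requested binding cost", {
  # no planted effect: mean score near 0
  raw_scores <- function(tab) {
    vapply(unique(tab$participant), function(pid) {
      sub <- tab[tab$participant == pid, ]
      m <- tapply(sub$rt2, sub$condition, mean)
      binding_score(m)
    }, 0)
  }
  tab0 <- generate_behavior(behavior_sim_params(
    n_participants = c(HC = 200), binding_cost = 0, binding_cost_sd = 0,
    seed = 11))
  s0 <- raw_scores(tab0)
  expect_lt(abs(mean(s0)), 3 * sd(s0) / sqrt(length(s0)))

  # planted 35 ms cost: expected score 2 * 35 = 70 ms
  tab <- generate_behavior(behavior_sim_params(n_participants = c(HC = 500),
                                               binding_cost = 35, seed = 12))
  s <- raw_scores(tab)
  expect_lt(abs(mean(s) - 70), 3 * sd(s) / sqrt(length(s)))
})

test_that("behavioral simulator is deterministic under its seed", {
  p <- behavior_sim_params(n_participants = c(GTS = 3, HC = 2), seed = 99)
  expect_identical(generate_behavior(p), generate_behavior(p))
})

test_that("epoch time axis covers [-7000, 2000) ms at 256 Hz", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 5, freq = 6, amplitude = 50)),
                      trials_per_condition = 2, seed = 1)
  ep <- generate_eeg(p, lf)
  expect_equal(dim(ep$data)[3], 2304L)
  times <- ep$t0_offset + (seq_len(2304) - 1) * 1000 / ep$sfreq
  expect_equal(times[1], -7000)
  expect_equal(times[2304], 2000 - 1000 / 256)
})

test_that("a single noiseless source gives a rank-1 sensor covariance", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 20, freq = 10,
                                amplitude = amp_matrix(0, list(period = "post_s2", amp = 50)))),
                      noise_sd = 0, trials_per_condition = 2, seed = 5)
  ep <- generate_eeg(p, lf)
  times <- ep$t0_offset + (seq_len(dim(ep$data)[3]) - 1) * 1000 / ep$sfreq
  idx <- which(times >= 0 & times < 1000)
  x <- ep$data[1, , idx]
  ev <- eigen(tcrossprod(x - rowMeans(x)), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1], 0)
  expect_lt(ev[2] / ev[1], 1e-12)
})

test_that("doubling source amplitude quadruples sensor band power", {
  lf <- fix_leadfield()
  mk <- function(a, seed) {
    p <- eeg_sim_params(list(list(voxel = 20, freq = 10,
                                  amplitude = amp_matrix(0, list(period = "post_s2", amp = a)))),
                        noise_sd = 0, amp_cv = 0, trials_per_condition = 1,
                        seed = seed)
    generate_eeg(p, lf)
  }
  ep1 <- mk(25, 3)
  ep2 <- mk(50, 3)  # same seed: same phases
  pw <- function(ep) {
    tf <- morlet_tfr(ep, c(9, 10, 11))
    mean(band_power(tf, c(9, 11), c(100, 900)))
  }
  expect_equal(pw(ep2) / pw(ep1), 4, tolerance = 0.01)
})

test_that("planted pre/post coupling appears in the drawn amplitude sequences", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(
    list(list(voxel = 10, freq = 6,
              amplitude = amp_matrix(0, list(period = "post_s1", amp = 60))),
         list(voxel = 30, freq = 6,
              amplitude = amp_matrix(0, list(period = "post_s2", amp = 60)))),
    coupling = list(pre_source = 1, pre_period = "post_s1",
                    post_source = 2, post_period = "post_s2", rho = 0.7),
    trials_per_condition = 50, seed = 21)
  ep <- generate_eeg(p, lf)
  a <- attr(ep, "amplitudes")
  r <- cor(a[, 1, "post_s1"], a[, 2, "post_s2"])
  n <- dim(a)[1]
  ci <- tanh(atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3))
  expect_equal(n, 200L)
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
})

test_that("EEG simulation is deterministic and validates source voxels", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(list(list(voxel = 5, freq = 6, amplitude = 50)),
                      trials_per_condition = 2, seed = 4)
  expect_equal(generate_eeg(p, lf)$data, generate_eeg(p, lf)$data)
  p_bad <- eeg_sim_params(list(list(voxel = 1e6, freq = 6, amplitude = 50)),
                          trials_per_condition = 2, seed = 4)
  expect_error(generate_eeg(p_bad, lf), "outside grid")
  expect_error(eeg_sim_params(list(list(voxel = 1, freq = 6)),
                              coupling = list(pre_source = 1, pre_period = "post_s1",
                                              post_source = 1, post_period = "post_s2",
                                              rho = 1.2)),
               "rho")
})

test_that("participant-level coupling propagates through simulate_study", {
  lf <- fix_leadfield()
  p <- eeg_sim_params(
    list(list(voxel = 10, freq = 6,
              amplitude = amp_matrix(0, list(period = "post_s1", amp = 60))),
         list(voxel = 30, freq = 6,
              amplitude = amp_matrix(0, list(period = "post_s2", amp = 60)))),
    coupling = list(pre_source = 1, pre_period = "post_s1",
                    post_source = 2, post_period = "post_s2", rho = 0.7),
    trials_per_condition = 1, noise_sd = 0.5, seed = 31)
  study <- simulate_study(p, lf, c(HC = 3, GTS = 2))
  expect_named(study, c("hc001", "hc002", "hc003", "gts001", "gts002"))
  expect_equal(vapply(study, function(e) e$group, ""),
               c(hc001 = "HC", hc002 = "HC", hc003 = "HC",
                 gts001 = "GTS", gts002 = "GTS"))
  sc <- attr(study, "scales")
  expect_equal(dim(sc), c(5L, 2L, 3L))
})
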