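make_table <- function(rt2, s1_correct = TRUE, s2_correct = TRUE,
                       participant = "p01", condition = "RRFR") {
  n <- length(rt2)
  data.frame(participant = participant, group = "HC",
             condition = rep_len(condition, n), rt1 = 300, rt2 = rt2,
             s1_correct = rep_len(s1_correct, n),
             s2_correct = rep_len(s2_correct, n))
}

test_that("trial filtering applies the RT floor and Tukey upper fence", {
  # 150 ms trial excluded by the floor
  tab <- make_table(c(150, rep(400, 7)))
  out <- filter_trials(tab)
  expect_false(150 %in% out$rt2)

  # hand-computed fence on {300..360, 2000}: Q1 = 317.5, Q3 = 352.5,
  # fence = 352.5 + 1.5 * 35 = 405 -> 2000 excluded
  tab2 <- make_table(c(300, 310, 320, 330, 340, 350, 360, 2000))
  out2 <- filter_trials(tab2)
  expect_setequal(out2$rt2, c(300, 310, 320, 330, 340, 350, 360))

  # identical RTs: IQR 0, fence equals the common value, nothing excluded
  tab3 <- make_table(rep(500, 10))
  expect_equal(nrow(filter_trials(tab3)), 10)

  # S1-incorrect trials are dropped outright
  tab4 <- rbind(make_table(rep(400, 6)), make_table(450, s1_correct = FALSE))
  expect_equal(nrow(filter_trials(tab4)), 6)

  # too few trials: fence skipped, participant flagged
  tab5 <- make_table(c(400, 2000, 410))
  out5 <- filter_trials(tab5)
  expect_equal(nrow(out5), 3)
  expect_equal(attr(out5, "fence_skipped"), "p01")
})

test_that("binding score formula and invariances", {
  expect_equal(binding_score(c(RRFA = 500, RRFR = 450, RAFA = 460, RAFR = 495)), 85)
  m <- c(RRFA = 480, RRFR = 480, RAFA = 480, RAFR = 480)
  expect_equal(binding_score(m), 0)
  expect_equal(binding_score(m + 123), binding_score(m))
  expect_error(binding_score(c(RRFA = 1, RRFR = 2, RAFA = 3)), "four condition")
})

test_that("one-sample t reproduces published summary statistics", {
  cases <- list(c(58.14, 92.31, 62, 4.96, 0.63),
                c(70.93, 85.56, 54, 6.09, 0.83),
                c(18.06, 17.36, 62, 8.19, 1.04),
                c(21.48, 17.16, 54, 9.20, 1.25))
  for (cs in cases) {
    r <- one_sample_t(mean = cs[1], sd = cs[2], n = cs[3])
    expect_equal(round(r$t, 2), cs[4])
    expect_equal(round(r$dz, 2), cs[5])
    expect_equal(r$df, cs[3] - 1)
  }
  expect_equal(one_sample_t(mean = 0, sd = 5, n = 10)$t, 0)
  expect_error(one_sample_t(mean = 1, sd = 0, n = 10), "sd")

  # data overload agrees with the summary-statistic overload
  set.seed(3)
  x <- rnorm(40, 1)
  a <- one_sample_t(x)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = 40)
  expect_equal(a$t, b$t)
  expect_equal(a$t, unname(t.test(x)$statistic))
})

test_that("Welch t statistic behaves correctly", {
  expect_equal(welch_t(5, 2, 10, 5, 2, 10)$t, 0)
  # equal variances, equal n: equals the pooled t
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  w <- welch_t(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  welch <- t.test(x, y)
  expect_equal(w$t, unname(welch$statistic))
  expect_equal(w$df, unname(welch$parameter))
  # variance -> 0 drives |t| up monotonically
  ts <- vapply(c(1, 0.5, 0.1, 0.01), function(s) abs(welch_t(1, s, 10, 0, s, 10)$t), 0)
  expect_true(all(diff(ts) > 0))
  expect_error(welch_t(1, 0, 10, 0, 0, 10), "zero variance")
})

test_that("Yates-corrected chi-square reproduces the published 2x2 tables", {
  expect_equal(round(chi2_2x2(35, 19, 37, 25)$chi2, 2), 0.14)
  expect_equal(round(chi2_2x2(46, 7, 56, 6)$chi2, 2), 0.09)
  expect_equal(round(chi2_2x2(15, 38, 2, 60)$chi2, 2), 12.34)

  # balanced table: 0 either way (the corrected form is floored at 0)
  expect_equal(chi2_2x2(10, 10, 10, 10, continuity = FALSE)$chi2, 0)
  expect_equal(chi2_2x2(10, 10, 10, 10)$chi2, 0)

  # invariant under simultaneous row and column swap
  expect_equal(chi2_2x2(15, 38, 2, 60)$chi2, chi2_2x2(60, 2, 38, 15)$chi2)
  # agrees with the standard implementation
  expect_equal(chi2_2x2(15, 38, 2, 60)$chi2,
               unname(chisq.test(rbind(c(15, 38), c(2, 60)))$statistic))
  expect_error(chi2_2x2(0, 0, 5, 5), "margins")
})

anova_cells <- function(y, groups) {
  # y: subjects x 4 matrix (RRFR, RRFA, RAFR, RAFA)
  n <- nrow(y)
  data.frame(participant = rep(sprintf("s%02d", 1:n), each = 4),
             group = rep(groups, each = 4),
             response = rep(c("RR", "RR", "RA", "RA"), n),
             feature = rep(c("FR", "FA", "FR", "FA"), n),
             value = as.vector(t(y)))
}

test_that("mixed ANOVA matches aov on balanced equal-n data", {
  set.seed(9)
  n <- 8
  y <- matrix(rnorm(4 * 2 * n), ncol = 4) +
    outer(rep(1, 2 * n), c(1, 0, 0, 0.5))
  groups <- rep(c("A", "B"), each = n)
  mine <- mixed_anova_2x2x2(anova_cells(y, groups))
  d <- anova_cells(y, groups)
  ref <- summary(aov(value ~ group * response * feature +
                       Error(participant / (response * feature)), data = d))
  get_f <- function(stratum, term) {
    tab <- ref[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(mine$F[mine$effect == "group"], get_f("Error: participant", "group"))
  expect_equal(mine$F[mine$effect == "response"],
               get_f("Error: participant:response", "response"))
  expect_equal(mine$F[mine$effect == "response:feature"],
               get_f("Error: participant:response:feature", "response:feature"))
  expect_equal(mine$F[mine$effect == "response:feature:group"],
               get_f("Error: participant:response:feature", "group:response:feature"))
})

test_that("mixed ANOVA sums of squares match a hand-computed toy decomposition", {
  # two participants per group, integer cell means
  y <- rbind(c(10, 8, 6, 4),    # s1, group A
             c(12, 10, 8, 6),   # s2, group A
             c(9, 9, 9, 9),     # s3, group B
             c(7, 9, 11, 13))   # s4, group B
  mine <- mixed_anova_2x2x2(anova_cells(y, c("A", "A", "B", "B")))
  ss <- attr(mine, "ss")
  # hand computation: subject means 7, 9, 9, 10; group means 8, 9.5;
  # SS_group = 4 * (8 - 9.5)^2 / (1/2 + 1/2) * ... = (8-9.5)^2/(1/2+1/2)*4 = 9
  expect_equal(ss$mean$between, 9)
  # R contrast (mean RR - mean RA) per subject: 4, 4, 0, -4; group means 4, -2
  expect_equal(ss$R$main, (1)^2 / ((1 / 4) * (1 / 2 + 1 / 2)), tolerance = 1e-12)
  expect_equal(ss$R$between, (4 - (-2))^2 / (1 / 2 + 1 / 2))
  expect_equal(ss$R$err, (4 - 4)^2 + (4 - 4)^2 + (0 - (-2))^2 + (-4 - (-2))^2)
  # RF contrast (RRFR - RRFA - RAFR + RAFA) per subject: 0, 0, 0, 0
  expect_equal(ss$RF$main, 0)
  expect_equal(mine$F[mine$effect == "response:feature"], 0)
})

test_that("mixed ANOVA handles degenerate and incomplete input", {
  # zero between-condition variance: all within-effect F are 0
  y <- matrix(5, nrow = 4, ncol = 4) + c(0, 1, 2, 3)
  res <- mixed_anova_2x2x2(anova_cells(y, c("A", "A", "B", "B")))
  for (eff in c("response", "feature", "response:feature")) {
    expect_equal(res$F[res$effect == eff], 0)
  }
  # a participant missing a cell is excluded with a warning
  d <- anova_cells(matrix(rnorm(16), 4), c("A", "A", "B", "B"))
  d <- d[-1, ]
  expect_warning(res2 <- mixed_anova_2x2x2(d), "missing cells")
})

test_that("planted crossover interaction is detected; null 3-way stays null", {
  set.seed(15)
  p3 <- replicate(40, {
    n <- 10
    y <- matrix(rnorm(4 * 2 * n, sd = 1), ncol = 4) +
      outer(rep(1, 2 * n), c(1, -1, -1, 1))  # response x feature crossover
    res <- mixed_anova_2x2x2(anova_cells(y, rep(c("A", "B"), each = n)))
    c(int = res$F[res$effect == "response:feature"],
      three_p = res$p[res$effect == "response:feature:group"])
  })
  expect_true(all(p3["int", ] > qf(0.999, 1, 18)))
  # 3-way p-values approximately uniform: rejection rate near alpha
  expect_lt(mean(p3["three_p", ] < 0.05), 0.25)
  expect_gt(mean(p3["three_p", ] < 0.5), 0.2)
})

test_that("binding_results computes per-participant scores on filtered trials", {
  tab <- generate_behavior(behavior_sim_params(n_participants = c(GTS = 4, HC = 4),
                                               seed = 42))
  br <- binding_results(filter_trials(tab))
  expect_equal(nrow(br), 8)
  expect_true(all(c("rt_binding_score", "err_binding_score") %in% names(br)))
  err_cols <- as.matrix(br[, paste0("err_", c("RRFR", "RRFA", "RAFR", "RAFA"))])
  expect_true(all(err_cols >= 0 & err_cols <= 100))
})
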