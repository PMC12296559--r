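# Behavioral analysis: trial filtering, binding scores and group statistics.

#' Filter behavioral trials
#'
#' Marks trials usable for the RT and error-rate analyses following the
#' standard exclusion scheme: trials with an incorrect or missed S1 response
#' are dropped outright; S2 responses faster than `rt_floor` (200 ms) are
#' dropped; and, per participant, S2 RTs above the Tukey upper fence
#' Q3 + 1.5 IQR (quartiles by linear interpolation, the type-7 convention,
#' configurable via `qtype`) are dropped. RT analyses additionally use only
#' S2-correct trials (`use_rt`); error-rate analyses keep S2-incorrect trials
#' (`use_err`). Participants with fewer than `min_trials` trials after the
#' floor filter are flagged and their fence is skipped.
#'
#' @param table trial table as returned by [generate_behavior()].
#' @param rt_floor minimum S2 RT in ms (default 200).
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @param qtype quantile type passed to [stats::quantile()] (default 7).
#' @param min_trials minimum retained trials needed to compute a fence.
#' @return the table restricted to S1-correct, floor- and fence-passing
#'   trials, with logical columns `use_rt` and `use_err` added; participants
#'   whose fence was skipped are listed in `attr(, "fence_skipped")`.
#' @export
filter_trials <- function(table, rt_floor = 200, fence_k = 1.5, qtype = 7,
                          min_trials = 4L) {
  assert_that(nrow(table) > 0, "empty trial table")
  keep <- table$s1_correct & !is.na(table$rt2) & table$rt2 >= rt_floor
  tab <- table[keep, , drop = FALSE]
  skipped <- character(0)
  sel <- logical(nrow(tab))
  for (pid in unique(tab$participant)) {
    i <- which(tab$participant == pid)
    rt <- tab$rt2[i]
    if (length(rt) < min_trials) {
      skipped <- c(skipped, pid)
      sel[i] <- TRUE
      next
    }
    q <- stats::quantile(rt, c(0.25, 0.75), type = qtype, names = FALSE)
    fence <- q[2] + fence_k * (q[2] - q[1])
    sel[i] <- rt <= fence
  }
  out <- tab[sel, , drop = FALSE]
  out$use_rt <- out$s2_correct
  out$use_err <- TRUE
  rownames(out) <- NULL
  attr(out, "fence_skipped") <- skipped
  out
}

#' Binding score from four condition means
#'
#' `((RRFA - RRFR) + (RAFR - RAFA))`: the summed cost of partial repetition
#' under response repetition and response alternation. Applies identically to
#' mean RTs (ms) and to error rates (percentage points). Invariant to adding
#' a constant to all four means.
#'
#' @param cond_means named numeric vector with elements `RRFA`, `RRFR`,
#'   `RAFR`, `RAFA`.
#' @return the binding score.
#' @export
binding_score <- function(cond_means) {
  need <- c("RRFA", "RRFR", "RAFR", "RAFA")
  assert_that(all(need %in% names(cond_means)) && !anyNA(cond_means[need]),
              "cond_means must supply all four condition means (RRFA, RRFR, RAFR, RAFA)")
  unname((cond_means["RRFA"] - cond_means["RRFR"]) +
           (cond_means["RAFR"] - cond_means["RAFA"]))
}

#' Per-participant condition means, error rates and binding scores
#'
#' @param table a filtered trial table from [filter_trials()].
#' @return data.frame with one row per participant: `participant`, `group`,
#'   mean RT per condition (`rt_RRFR`, ...), error rate per condition in
#'   percent (`err_RRFR`, ...), `rt_binding_score` (ms) and
#'   `err_binding_score` (percentage points).
#' @export
binding_results <- function(table) {
  assert_that(all(c("use_rt", "use_err") %in% names(table)),
              "run filter_trials() first")
  out <- list()
  for (pid in unique(table$participant)) {
    sub <- table[table$participant == pid, ]
    rt_means <- err_rates <- stats::setNames(rep(NA_real_, 4), CONDITIONS)
    for (cond in CONDITIONS) {
      rt_tr <- sub$rt2[sub$condition == cond & sub$use_rt]
      err_tr <- sub$s2_correct[sub$condition == cond & sub$use_err]
      if (length(rt_tr) > 0) rt_means[cond] <- mean(rt_tr)
      if (length(err_tr) > 0) err_rates[cond] <- 100 * mean(!err_tr)
    }
    row <- data.frame(participant = pid, group = sub$group[1])
    for (cond in CONDITIONS) row[[paste0("rt_", cond)]] <- rt_means[cond]
    for (cond in CONDITIONS) row[[paste0("err_", cond)]] <- err_rates[cond]
    row$rt_binding_score <- if (anyNA(rt_means)) NA_real_ else binding_score(rt_means)
    row$err_binding_score <- if (anyNA(err_rates)) NA_real_ else binding_score(err_rates)
    out[[pid]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sample t test against zero, with dz effect size
#'
#' Either supply a data vector `x`, or summary statistics `mean`, `sd`, `n`
#' (as printed in a results table). `t = mean / (sd / sqrt(n))`,
#' `dz = mean / sd`, `df = n - 1`.
#'
#' @param x numeric data vector (optional).
#' @param mean,sd,n summary statistics (used when `x` is missing).
#' @return list with `t`, `df`, `dz`, `p` (two-sided).
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  assert_that(!is.null(mean) && !is.null(sd) && !is.null(n),
              "supply either x or (mean, sd, n)")
  assert_that(n >= 2, "need n >= 2")
  assert_that(sd > 0, "sd must be positive")
  t <- mean / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, dz = mean / sd,
       p = 2 * stats::pt(-abs(t), df))
}

#' Welch two-sample t test from summary statistics
#'
#' Standard Welch statistic with Satterthwaite degrees of freedom; also
#' accepts two data vectors.
#'
#' @param m1,s1,n1 mean, SD and size of group 1 (or `m1` = data vector).
#' @param m2,s2,n2 same for group 2 (or `m2` = data vector).
#' @return list with `t`, `df`, `p` (two-sided) and Cohen's `d`
#'   (pooled-SD standardizer).
#' @export
welch_t <- function(m1, s1 = NULL, n1 = NULL, m2 = NULL, s2 = NULL, n2 = NULL) {
  if (length(m1) > 1) {
    x <- m1[!is.na(m1)]
    y <- if (length(s1) > 1) s1[!is.na(s1)] else m2[!is.na(m2)]
    n1 <- length(x); n2 <- length(y)
    s1 <- stats::sd(x); s2 <- stats::sd(y)
    m1 <- mean(x); m2 <- mean(y)
  }
  assert_that(n1 >= 2 && n2 >= 2, "need n >= 2 in both groups")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  assert_that(v1 + v2 > 0, "both groups have zero variance")
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), d = (m1 - m2) / sp)
}

#' 2x2 chi-square test of independence
#'
#' For the table `rbind(c(a, b), c(c, d))`. With `continuity = TRUE`
#' (default) the Yates-corrected statistic
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` is returned (floored at
#' zero when the correction exceeds `|ad - bc|`); otherwise the uncorrected
#' Pearson statistic.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param continuity apply the Yates correction (default `TRUE`).
#' @return list with `chi2`, `df = 1` and `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, continuity = TRUE) {
  counts <- c(a, b, c, d)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  assert_that(all(margins > 0), "all row and column margins must be positive")
  det <- abs(a * d - b * c)
  adj <- if (continuity) max(0, det - n / 2) else det
  chi2 <- n * adj^2 / prod(margins)
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Mixed 2x2x2 ANOVA (group x response relation x feature relation)
#'
#' Repeated-measures ANOVA for one between-subject factor (group) and two
#' within-subject factors with two levels each, computed by explicit
#' per-subject contrast decomposition with unweighted (Type III) marginal
#' means — exact for the balanced within-subject design. Generalized eta
#' squared follows the Bakeman/Olejnik convention:
#' `SS_effect / (SS_effect + all subject-related error SS)`.
#'
#' @param cells data.frame with columns `participant`, `group`, `response`
#'   (`"RR"`/`"RA"`), `feature` (`"FR"`/`"FA"`), `value`: one row per cell.
#'   Participants with missing cells are excluded with a warning.
#' @return data.frame with one row per effect (`group`, `response`,
#'   `feature`, `response:feature`, the group interactions) giving `F`,
#'   `df1`, `df2`, `p` and `ges`.
#' @export
mixed_anova_2x2x2 <- function(cells) {
  need <- c("participant", "group", "response", "feature", "value")
  assert_that(all(need %in% names(cells)), "cells must have columns %s",
              paste(need, collapse = ", "))
  # wide: one row per participant, 4 cell means
  key <- interaction(cells$response, cells$feature, sep = "")
  wide <- list()
  for (pid in unique(cells$participant)) {
    sub <- cells[cells$participant == pid, ]
    v <- stats::setNames(rep(NA_real_, 4), c("RRFR", "RRFA", "RAFR", "RAFA"))
    for (i in seq_len(nrow(sub))) {
      v[paste0(sub$response[i], sub$feature[i])] <- sub$value[i]
    }
    if (anyNA(v)) {
      warning("participant ", pid, " has missing cells; excluded")
      next
    }
    wide[[pid]] <- data.frame(participant = pid, group = sub$group[1], t(v))
  }
  w <- do.call(rbind, wide)
  groups <- unique(w$group)
  assert_that(length(groups) %in% c(1L, 2L), "at most two groups are supported")
  n_g <- table(factor(w$group, levels = groups))
  n_tot <- nrow(w)

  y <- as.matrix(w[, c("RRFR", "RRFA", "RAFR", "RAFA")])
  # per-subject scores and their contrast-vector squared norms
  scores <- list(
    mean = list(v = rowMeans(y), nrm = 1 / 4),
    R    = list(v = (y[, "RRFR"] + y[, "RRFA"] - y[, "RAFR"] - y[, "RAFA"]) / 2, nrm = 1),
    F    = list(v = (y[, "RRFR"] + y[, "RAFR"] - y[, "RRFA"] - y[, "RAFA"]) / 2, nrm = 1),
    RF   = list(v = y[, "RRFR"] - y[, "RRFA"] - y[, "RAFR"] + y[, "RAFA"], nrm = 4)
  )
  g_idx <- lapply(groups, function(g) which(w$group == g))

  ss <- list()
  for (nm in names(scores)) {
    sc <- scores[[nm]]
    gm <- vapply(g_idx, function(i) mean(sc$v[i]), 0)
    err <- sum(vapply(seq_along(g_idx),
                      function(k) sum((sc$v[g_idx[[k]]] - gm[k])^2), 0))
    if (length(groups) == 2L) {
      between <- (gm[1] - gm[2])^2 / (1 / n_g[1] + 1 / n_g[2])
      grand <- mean(gm)
      main <- grand^2 / ((1 / length(groups)^2) * sum(1 / n_g))
    } else {
      between <- 0
      main <- n_tot * gm[1]^2
    }
    ss[[nm]] <- list(main = as.numeric(main / sc$nrm),
                     between = as.numeric(between / sc$nrm),
                     err = as.numeric(err / sc$nrm))
  }

  df_err <- n_tot - length(groups)
  err_total <- ss$mean$err + ss$R$err + ss$F$err + ss$RF$err
  row <- function(effect, ss_eff, ss_err) {
    ms_err <- ss_err / df_err
    f <- if (ms_err > 0) (ss_eff / 1) / ms_err else 0
    data.frame(effect = effect, F = f, df1 = 1, df2 = df_err,
               p = stats::pf(f, 1, df_err, lower.tail = FALSE),
               ges = if (ss_eff + err_total > 0) ss_eff / (ss_eff + err_total) else 0)
  }
  out <- rbind(
    if (length(groups) == 2L) row("group", ss$mean$between, ss$mean$err),
    row("response", ss$R$main, ss$R$err),
    if (length(groups) == 2L) row("response:group", ss$R$between, ss$R$err),
    row("feature", ss$F$main, ss$F$err),
    if (length(groups) == 2L) row("feature:group", ss$F$between, ss$F$err),
    row("response:feature", ss$RF$main, ss$RF$err),
    if (length(groups) == 2L) row("response:feature:group", ss$RF$between, ss$RF$err))
  rownames(out) <- NULL
  attr(out, "ss") <- ss
  out
}
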