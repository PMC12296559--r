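# Synthetic behavioral tables and forward-modelled EEG epochs carrying the
# statistical structure the analysis assumes: a planted partial-repetition
# cost in RT/error rates, and condition- and period-dependent oscillatory
# sources with a controllable pre/post amplitude coupling.

CONDITIONS <- c("RRFR", "RRFA", "RAFR", "RAFA")
BINDING_CONDS <- c("RRFA", "RAFR")  # partial-repetition (reconfiguration) cells

BANDS <- list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30))

# Default analysis periods (ms relative to S2), all half-open [a, b)
PERIODS <- list(post_s1 = c(-2500, -1500),
                pre_s2  = c(-1000, 0),
                post_s2 = c(0, 1000))

#' Parameters for the behavioral simulator
#'
#' Defaults reflect the prime-probe task design: 24 trials per condition
#' (384 trials over 16 conditions) and a planted partial-repetition cost
#' `binding_cost` added to the mean RT of the RRFA and RAFR cells, giving an
#' expected RT binding score of `2 * binding_cost`. RT noise is a shifted
#' lognormal (positive support, right skew); `binding_cost_sd` adds
#' between-participant variability in the planted effect.
#'
#' @param n_participants participants per group (named vector or scalar).
#' @param trials_per_condition trials in each of the four key cells.
#' @param base_rt mean S2 reaction time (ms) in the full-repetition /
#'   full-alternation cells.
#' @param binding_cost mean RT cost (ms) added to RRFA and RAFR.
#' @param binding_cost_sd between-participant SD of the cost (ms).
#' @param rt_sd within-cell trial-to-trial RT SD (ms).
#' @param rt_shift lognormal shift (ms), the minimum possible RT.
#' @param error_base S2 error probability in RRFR/RAFA.
#' @param error_binding_cost extra S2 error probability in RRFA/RAFR.
#' @param s1_accuracy probability of a correct S1 response.
#' @param seed integer RNG seed.
#' @return A list of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_participants = c(GTS = 54, HC = 62),
                                trials_per_condition = 24L,
                                base_rt = 450,
                                binding_cost = 35,
                                binding_cost_sd = 30,
                                rt_sd = 150,
                                rt_shift = 150,
                                error_base = 0.05,
                                error_binding_cost = 0.10,
                                s1_accuracy = 0.95,
                                seed = 1L) {
  assert_that(trials_per_condition >= 2, "need at least 2 trials per condition")
  assert_that(binding_cost >= 0, "binding_cost must be non-negative")
  probs <- c(error_base, error_base + error_binding_cost, s1_accuracy)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(rt_sd > 0 && base_rt > rt_shift, "need rt_sd > 0 and base_rt > rt_shift")
  if (is.null(names(n_participants))) {
    n_participants <- c(GTS = n_participants[1],
                        HC = if (length(n_participants) > 1) n_participants[2] else n_participants[1])
  }
  structure(as.list(environment()), class = "behavior_sim_params")
}

rlnorm_mean_sd <- function(n, mean, sd) {
  # lognormal draws with exact target mean and sd
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a behavioral trial table
#'
#' Generates per-trial S1/S2 reaction times and correctness for every
#' participant and condition under [behavior_sim_params()]. S2 RTs follow a
#' shifted lognormal whose mean is `base_rt` plus the binding cost in the
#' partial-repetition cells (RRFA, RAFR); S1 correctness and S2 errors are
#' Bernoulli. Deterministic under the seed.
#'
#' @param params a [behavior_sim_params()] object.
#' @return A `data.frame` (trial table) with columns `participant`, `group`,
#'   `condition`, `rt1`, `rt2`, `s1_correct`, `s2_correct`.
#' @export
generate_behavior <- function(params = behavior_sim_params()) {
  stopifnot(inherits(params, "behavior_sim_params"))
  with_seed(params$seed, {
    rows <- list()
    for (g in names(params$n_participants)) {
      for (p in seq_len(params$n_participants[[g]])) {
        pid <- sprintf("%s%03d", tolower(g), p)
        intercept <- rnorm(1, 0, 25)                 # participant speed offset
        cost_p <- rnorm(1, params$binding_cost, params$binding_cost_sd)
        for (cond in CONDITIONS) {
          n <- params$trials_per_condition
          m <- params$base_rt + intercept +
            if (cond %in% BINDING_CONDS) cost_p else 0
          m <- max(m, params$rt_shift + 50)  # keep the lognormal mean positive
          rt2 <- params$rt_shift +
            rlnorm_mean_sd(n, m - params$rt_shift, params$rt_sd)
          p_err <- params$error_base +
            if (cond %in% BINDING_CONDS) params$error_binding_cost else 0
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pid, group = g, condition = cond,
            rt1 = params$rt_shift + rlnorm_mean_sd(n, 300, 80),
            rt2 = rt2,
            s1_correct = runif(n) < params$s1_accuracy,
            s2_correct = runif(n) >= p_err)
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })
}

#' Parameters for the EEG simulator
#'
#' Each source is an oscillating dipole at a grid voxel, active in one or more
#' of the post-S1 (-2500 to -1500 ms), pre-S2 (-1000 to 0 ms) and post-S2
#' (0 to 1000 ms) periods with a per-condition, per-period mean amplitude.
#' Trial amplitudes fluctuate around the mean (`amp_cv`), the phase is drawn
#' uniformly per trial, and an optional coupling ties the amplitude latents of
#' one source/period to another via a shared Gaussian factor with loading
#' sqrt(rho), so the across-trial amplitude correlation equals `rho` exactly
#' in expectation.
#'
#' @param sources list of source specs, each a list with `voxel` (grid index),
#'   `freq` (Hz), optional `orientation` (3-vector dipole moment direction;
#'   default a deterministic tangential unit vector), and `amplitude`: either
#'   a scalar (nA m), or a conditions x periods matrix (rownames from
#'   `RRFR/RRFA/RAFR/RAFA`, colnames from `post_s1/pre_s2/post_s2`).
#' @param coupling `NULL`, or a list with `pre_source`, `pre_period`,
#'   `post_source`, `post_period`, `rho` in [-1, 1].
#' @param amp_cv coefficient of variation of trial amplitudes.
#' @param participant_cv coefficient of variation of per-participant
#'   amplitude scaling factors in [simulate_study()]; the coupling is applied
#'   at that level too, so participant-mean power carries it.
#' @param noise_sd sensor white-noise SD in microvolts.
#' @param sfreq sampling rate (Hz), default 256.
#' @param epoch_ms epoch window (ms relative to S2), default c(-7000, 2000),
#'   half-open, giving 2304 samples at 256 Hz.
#' @param trials_per_condition trials per condition.
#' @param seed integer RNG seed.
#' @return A list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(sources,
                           coupling = NULL,
                           amp_cv = 0.3,
                           participant_cv = 0.3,
                           noise_sd = 1,
                           sfreq = 256,
                           epoch_ms = c(-7000, 2000),
                           trials_per_condition = 24L,
                           seed = 1L) {
  if (!is.null(coupling)) {
    assert_that(abs(coupling$rho) <= 1, "|rho| must not exceed 1")
    assert_that(all(c(coupling$pre_period, coupling$post_period) %in% names(PERIODS)),
                "coupling periods must name post_s1, pre_s2 or post_s2")
  }
  assert_that(sfreq > 0 && epoch_ms[2] > epoch_ms[1], "invalid sampling/epoch spec")
  for (src in sources) {
    assert_that(!is.null(src$voxel) && !is.null(src$freq), "source needs voxel and freq")
  }
  structure(as.list(environment()), class = "eeg_sim_params")
}

# Deterministic unit vector tangential to the radial direction at a voxel
# (EEG is most sensitive to tangential moments); any vector at the origin.
default_orientation <- function(pos) {
  r <- sqrt(sum(pos^2))
  if (r < 1e-12) return(c(1, 0, 0))
  rhat <- pos / r
  e <- diag(3)[, which.min(abs(rhat))]
  t <- e - sum(e * rhat) * rhat
  t / sqrt(sum(t^2))
}

source_amplitude <- function(src, cond, period) {
  a <- src$amplitude
  if (is.null(a)) return(50)
  if (is.matrix(a)) {
    row <- if (cond %in% rownames(a)) cond else rownames(a)[1]
    col <- if (period %in% colnames(a)) period else return(0)
    return(a[row, col])
  }
  a
}

#' Simulate forward-modelled EEG epochs for one participant
#'
#' Builds per-trial source signals (band-limited sinusoids windowed to their
#' active periods, half-open in time), projects them through the lead field,
#' converts to microvolts and adds white sensor noise. Condition labels cycle
#' through the four key cells. The drawn per-trial amplitudes are returned in
#' `attr(, "amplitudes")` (trials x sources x periods) so planted couplings
#' can be checked directly.
#'
#' @param params an [eeg_sim_params()] object.
#' @param leadfield a [spherical_leadfield()] object.
#' @param participant participant id string.
#' @param group group label (`"GTS"` or `"HC"`).
#' @param amp_scale optional sources x periods matrix of amplitude
#'   multipliers (participant-level scaling; default all 1).
#' @return An [epoch_set()] with dimensions trials x channels x samples.
#' @export
generate_eeg <- function(params, leadfield, participant = "sim001", group = "HC",
                         amp_scale = NULL) {
  stopifnot(inherits(params, "eeg_sim_params"))
  n_vox <- dim(leadfield$gain)[2]
  for (src in params$sources) {
    assert_that(src$voxel >= 1 && src$voxel <= n_vox,
                "source voxel %d outside grid (1..%d)", src$voxel, n_vox)
  }
  with_seed(params$seed, {
    n_ch <- dim(leadfield$gain)[1]
    dt <- 1000 / params$sfreq
    times <- seq(params$epoch_ms[1], params$epoch_ms[2] - dt, by = dt)
    n_t <- length(times)
    conds <- rep(CONDITIONS, each = params$trials_per_condition)
    n_trials <- length(conds)
    n_src <- length(params$sources)

    # amplitude latents: z[trial, source, period]; coupling via shared factor
    z <- array(rnorm(n_trials * n_src * 3), dim = c(n_trials, n_src, 3),
               dimnames = list(NULL, NULL, names(PERIODS)))
    if (!is.null(params$coupling)) {
      cp <- params$coupling
      rho <- cp$rho
      shared <- rnorm(n_trials)
      mix <- function(sh, eps) sqrt(abs(rho)) * sh + sqrt(1 - abs(rho)) * eps
      z[, cp$pre_source, cp$pre_period] <-
        mix(shared, rnorm(n_trials))
      z[, cp$post_source, cp$post_period] <-
        mix(sign(rho) * shared, rnorm(n_trials))
    }

    gains <- vapply(params$sources, function(src) {
      ori <- if (is.null(src$orientation)) {
        default_orientation(leadfield$grid$positions[src$voxel, ])
      } else {
        src$orientation / sqrt(sum(src$orientation^2))
      }
      leadfield$gain[, src$voxel, ] %*% ori
    }, numeric(n_ch))                               # channels x sources

    amps <- array(0, dim = c(n_trials, n_src, 3),
                  dimnames = list(NULL, NULL, names(PERIODS)))
    data <- array(0, dim = c(n_trials, n_ch, n_t))
    t_s <- times / 1000
    for (tr in seq_len(n_trials)) {
      src_sum <- matrix(0, n_ch, n_t)
      for (si in seq_len(n_src)) {
        src <- params$sources[[si]]
        wave <- numeric(n_t)
        for (per_i in seq_along(PERIODS)) {
          pname <- names(PERIODS)[per_i]
          base_amp <- source_amplitude(src, conds[tr], pname)
          if (!is.null(amp_scale)) base_amp <- base_amp * amp_scale[si, per_i]
          if (base_amp == 0) next
          a <- base_amp * (1 + params$amp_cv * z[tr, si, per_i])
          amps[tr, si, per_i] <- a
          idx <- window_samples(times, PERIODS[[pname]])
          phase <- runif(1, 0, 2 * pi)
          wave[idx] <- wave[idx] + a * sin(2 * pi * src$freq * t_s[idx] + phase)
        }
        # amplitude in nA m, gain in V/(A m) -> microvolts: 1e-9 * 1e6
        src_sum <- src_sum + outer(drop(gains[, si]), wave) * 1e-3
      }
      data[tr, , ] <- src_sum + matrix(rnorm(n_ch * n_t, 0, params$noise_sd),
                                       n_ch, n_t)
    }
    ep <- epoch_set(data, sfreq = params$sfreq, t0_offset = params$epoch_ms[1],
                    channels = dimnames(leadfield$gain)[[1]],
                    conditions = conds, participant = participant, group = group)
    attr(ep, "amplitudes") <- amps
    ep
  })
}

#' Simulate a multi-participant EEG study
#'
#' Calls [generate_eeg()] once per participant with participant-specific
#' seeds derived from `params$seed`. Every source/period mean amplitude is
#' scaled per participant by `1 + participant_cv * z` with independent
#' standard-normal latents; if `params$coupling` is set, the latents of the
#' coupled (source, period) pair share a common factor with loading
#' `sqrt(rho)`, so the planted correlation also holds across participants —
#' the observational unit of the pre/post correlation analysis.
#'
#' @param params an [eeg_sim_params()] object (its `seed` seeds the study).
#' @param leadfield a [spherical_leadfield()] object.
#' @param n_participants named vector, participants per group.
#' @return named list of epoch sets; per-participant amplitude scale
#'   matrices are kept in `attr(, "scales")`.
#' @export
simulate_study <- function(params, leadfield, n_participants = c(HC = 12)) {
  n_src <- length(params$sources)
  n_tot <- sum(n_participants)
  scales <- with_seed(params$seed, {
    z <- array(rnorm(n_tot * n_src * 3), dim = c(n_tot, n_src, 3),
               dimnames = list(NULL, NULL, names(PERIODS)))
    if (!is.null(params$coupling)) {
      cp <- params$coupling
      rho <- cp$rho
      shared <- rnorm(n_tot)
      mix <- function(sh, eps) sqrt(abs(rho)) * sh + sqrt(1 - abs(rho)) * eps
      z[, cp$pre_source, cp$pre_period] <- mix(shared, rnorm(n_tot))
      z[, cp$post_source, cp$post_period] <- mix(sign(rho) * shared, rnorm(n_tot))
    }
    1 + params$participant_cv * z
  })
  out <- list()
  k <- 0L
  for (g in names(n_participants)) {
    for (p in seq_len(n_participants[[g]])) {
      k <- k + 1L
      pp <- params
      pp$seed <- (params$seed * 1009L + k * 7919L) %% 2147483647L
      pid <- sprintf("%s%03d", tolower(g), p)
      out[[pid]] <- generate_eeg(pp, leadfield, participant = pid, group = g,
                                 amp_scale = matrix(scales[k, , ], n_src, 3))
    }
  }
  attr(out, "scales") <- scales
  out
}
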