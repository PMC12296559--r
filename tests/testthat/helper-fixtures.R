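# Shared fixtures, built once per test run. Sizes are kept small: a 24-channel
# Fibonacci cap and a 1.25 cm grid inside a 5 cm source sphere are enough to
# exercise every source-level code path.

fixture_env <- new.env()

fix_sensors <- function() {
  if (is.null(fixture_env$sensors)) fixture_env$sensors <- sensor_array(24)
  fixture_env$sensors
}

fix_grid <- function() {
  if (is.null(fixture_env$grid)) fixture_env$grid <- build_grid(0.05, 0.0125)
  fixture_env$grid
}

fix_leadfield <- function() {
  if (is.null(fixture_env$lf)) {
    fixture_env$lf <- spherical_leadfield(fix_grid(), fix_sensors())
  }
  fixture_env$lf
}

# amplitude matrix helper: condition x period means
amp_matrix <- function(default = 0, ...) {
  m <- matrix(default, 4, 3,
              dimnames = list(c("RRFR", "RRFA", "RAFR", "RAFA"),
                              c("post_s1", "pre_s2", "post_s2")))
  for (set in list(...)) m[set$cond %||% 1:4, set$period] <- set$amp
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sine-filled epoch set on the standard 9 s / 256 Hz axis
sine_epochs <- function(freq = 10, amp = 20, n_ch = 2, sfreq = 256,
                        epoch_ms = c(-7000, 2000), n_trials = 1) {
  t <- seq(epoch_ms[1], epoch_ms[2] - 1000 / sfreq, by = 1000 / sfreq) / 1000
  x <- amp * sin(2 * pi * freq * t)
  data <- array(rep(x, each = n_trials * n_ch),
                dim = c(n_trials, n_ch, length(t)))
  epoch_set(data, sfreq, epoch_ms[1], sprintf("c%02d", seq_len(n_ch)))
}

# independent oracle: surface potential by explicit Legendre recurrence
series_potential <- function(elec, dipole_pos, q, radius, conductivity,
                             n_terms = 300) {
  b <- sqrt(sum(dipole_pos^2))
  rhat <- elec / sqrt(sum(elec^2))
  ahat <- if (b > 0) dipole_pos / b else c(0, 0, 1)
  f <- b / radius
  u <- sum(rhat * ahat)
  A <- sum(q * ahat)
  B <- sum(q * rhat) - u * A
  P <- numeric(n_terms + 1)
  dP <- numeric(n_terms + 1)
  P[1] <- 1; P[2] <- u
  dP[1] <- 0; dP[2] <- 1
  for (n in 2:n_terms) {
    P[n + 1] <- ((2 * n - 1) * u * P[n] - (n - 1) * P[n - 1]) / n
    dP[n + 1] <- dP[n - 1] + (2 * n - 1) * P[n]
  }
  v <- 0
  for (n in 1:n_terms) {
    v <- v + (2 * n + 1) / n * f^(n - 1) * (n * A * P[n + 1] + B * dP[n + 1])
  }
  v / (4 * pi * conductivity * radius^2)
}
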