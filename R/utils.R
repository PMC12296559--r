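#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulation functions are deterministic
#' under their `seed` argument without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Sample indices of a half-open time window [a, b) in ms
#'
#' Times are expressed in ms relative to the S2 stimulus; the sample at `b`
#' is excluded so adjacent windows never share samples.
#' @noRd
window_samples <- function(times_ms, window_ms) {
  stopifnot(length(window_ms) == 2L, window_ms[2] > window_ms[1])
  which(times_ms >= window_ms[1] & times_ms < window_ms[2])
}

#' Time axis (ms, relative to S2) of an epoch set
#' @noRd
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$t0_offset + (seq_len(n) - 1L) * 1000 / epochs$sfreq
}

#' Running max / min over a fixed-width sample window (step 1)
#'
#' Sparse-table (doubling) scheme: O(n log w) fully vectorised, used by the
#' amplitude-based epoch rejection where brute-force windowing is too slow.
#' Returns a vector of length n - w + 1.
#' @noRd
running_max <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1L, w <= n)
  if (w == 1L) return(x)
  k <- floor(log2(w))
  m <- x
  len <- 1L
  while (2L * len <= w) {
    m <- pmax(m[seq_len(length(m) - len)], m[(len + 1L):length(m)])
    len <- 2L * len
  }
  # m[i] = max over [i, i+len-1]; combine two overlapping len-blocks
  if (len == w) return(m)
  off <- w - len
  pmax(m[seq_len(n - w + 1L)], m[(off + 1L):(n - len + 1L)])
}

#' @noRd
running_min <- function(x, w) -running_max(-x, w)

#' Stop unless a condition holds, with a formatted message
#' @noRd
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Euclidean norm of rows of a matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m^2))
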