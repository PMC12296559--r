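# Time-resolved Pearson correlation between pre-trial and post-trial cluster
# band power across participants, with Benjamini-Hochberg q-values.

#' Time-by-time correlation matrix between two cluster courses
#'
#' `r[i, j]` is the Pearson correlation, across participants, of pre-trial
#' power at time `i` with post-trial power at time `j`; two-sided p-values
#' come from the t transform `t = r sqrt((n-2)/(1-r^2))`. Cells involving a
#' zero-variance time point are undefined (`NA`) and excluded from the BH
#' family. One matrix is one FDR family (one cluster pair).
#'
#' @param pre participants x pre-times matrix of band power.
#' @param post participants x post-times matrix (same participants, same
#'   row order).
#' @param pre_times,post_times optional time labels (ms).
#' @return An object of class `corr_matrix`: `r`, `p`, `q` (pre-times x
#'   post-times), `n`, time labels.
#' @export
timewise_correlation <- function(pre, post, pre_times = NULL,
                                 post_times = NULL) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  assert_that(nrow(pre) == nrow(post),
              "pre and post must have the same participants")
  n <- nrow(pre)
  assert_that(n >= 4, "need at least 4 participants")
  sd_pre <- apply(pre, 2, stats::sd)
  sd_post <- apply(post, 2, stats::sd)
  r <- suppressWarnings(stats::cor(pre, post))
  r[sd_pre == 0, ] <- NA
  r[, sd_post == 0] <- NA
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), n - 2)
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p))
  dn <- list(pre_times, post_times)
  dimnames(r) <- dimnames(p) <- dimnames(q) <- dn
  structure(list(r = r, p = p, q = q, n = n,
                 pre_times = pre_times, post_times = post_times),
            class = "corr_matrix")
}

#' FDR significance mask of a correlation matrix
#'
#' @param corr a [timewise_correlation()] result.
#' @param alpha q-value threshold. The default 0.01 is the conservative
#'   threshold; 0.05 is also conventional — both are reported by the
#'   pipeline.
#' @return logical matrix, `TRUE` where `q < alpha` (`FALSE` for undefined
#'   cells).
#' @export
fdr_threshold <- function(corr, alpha = 0.01) {
  stopifnot(inherits(corr, "corr_matrix"))
  mask <- !is.na(corr$q) & corr$q < alpha
  mask
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d time points, n = %d participants; r in [%.2f, %.2f]; %d cells q < 0.05\n",
              nrow(x$r), ncol(x$r), x$n,
              min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE),
              sum(fdr_threshold(x, 0.05))))
  invisible(x)
}
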