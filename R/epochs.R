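# Epoch container, serialization and a minimal BrainVision reader.

VALID_CONDITIONS <- c("RRFR", "RRFA", "RAFR", "RAFA", "other")

#' Construct an epoched EEG container
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param t0_offset time (ms) of the first sample relative to the S2 stimulus
#'   (e.g. -7000 for a 9 s epoch ending 2 s after S2).
#' @param channels character vector of unique channel names.
#' @param conditions per-trial condition labels from
#'   `RRFR, RRFA, RAFR, RAFA, other`.
#' @param participant participant id.
#' @param group group label, `"GTS"` or `"HC"`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, t0_offset, channels,
                      conditions = rep("other", dim(data)[1]),
                      participant = "unknown", group = "HC") {
  assert_that(length(dim(data)) == 3, "data must be a trials x channels x samples array")
  assert_that(sfreq > 0, "sfreq must be positive")
  assert_that(length(channels) == dim(data)[2], "channel names must match data")
  assert_that(!anyDuplicated(channels), "channel names must be unique")
  assert_that(length(conditions) == dim(data)[1], "one condition label per trial")
  assert_that(all(conditions %in% VALID_CONDITIONS),
              "condition labels must come from {%s}", paste(VALID_CONDITIONS, collapse = ", "))
  structure(list(data = data, sfreq = sfreq, t0_offset = t0_offset,
                 channels = channels, conditions = conditions,
                 participant = participant, group = group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s (%s): %d trials x %d channels x %d samples @ %g Hz, t0 %g ms\n",
              x$participant, x$group, d[1], d[2], d[3], x$sfreq, x$t0_offset))
  invisible(x)
}

#' Subset an epoch set by trial
#' @param epochs an [epoch_set()].
#' @param trials integer or logical trial index.
#' @return an [epoch_set()].
#' @export
subset_trials <- function(epochs, trials) {
  epoch_set(epochs$data[trials, , , drop = FALSE], epochs$sfreq,
            epochs$t0_offset, epochs$channels, epochs$conditions[trials],
            epochs$participant, epochs$group)
}

#' Write / read the epoch container
#'
#' Single-file binary container using R serialization; the round trip is
#' bit-exact for data and metadata.
#' @param epochs an [epoch_set()].
#' @param path file path.
#' @return `read_epochs` returns the [epoch_set()]; `write_epochs` the path,
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(unclass(epochs), path, version = 3)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  epoch_set(x$data, x$sfreq, x$t0_offset, x$channels, x$conditions,
            x$participant, x$group)
}

# ---------------------------------------------------------------------------
# Minimal BrainVision (.vhdr / .vmrk / .eeg) ingestion: continuous data plus
# stimulus markers, epoched around a chosen marker. Supports the common
# IEEE_FLOAT_32 / INT_16 binary formats in MULTIPLEXED orientation.

parse_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln) && !is.null(sec)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording and cut epochs around a marker
#'
#' Reads the `.vhdr` header, the binary `.eeg` data file and the `.vmrk`
#' marker file, then extracts epochs of `epoch_ms` (half-open, ms) around
#' every marker whose description matches `marker`.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @param marker regular expression matched against marker descriptions
#'   (default `"S  2"`-style stimulus markers: `"^S"`).
#' @param epoch_ms epoch window in ms around the marker.
#' @param conditions optional per-epoch condition labels.
#' @return an [epoch_set()].
#' @export
read_brainvision <- function(vhdr_path, marker = "^S", epoch_ms = c(-7000, 2000),
                             conditions = NULL) {
  hdr <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  assert_that(!is.null(ci), "not a BrainVision header: %s", vhdr_path)
  assert_that(identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED"),
              "only MULTIPLEXED orientation is supported")
  n_ch <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)  # interval in microseconds
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")

  chan <- character(n_ch)
  res <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    spec <- strsplit(hdr[["Channel Infos"]][[sprintf("Ch%d", i)]], ",")[[1]]
    chan[i] <- spec[1]
    if (length(spec) >= 3 && nzchar(spec[3])) res[i] <- as.numeric(spec[3])
  }

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci$DataFile)
  n_bytes <- file.size(eeg_path)
  con <- file(eeg_path, "rb")
  on.exit(close(con), add = TRUE)
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(con, "numeric", n = n_bytes / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(con, "integer", n = n_bytes / 2, size = 2, endian = "little")
  } else {
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  }
  n_samp <- length(raw_vals) %/% n_ch
  cont <- matrix(raw_vals[seq_len(n_samp * n_ch)], nrow = n_ch)  # multiplexed
  cont <- cont * res

  vmrk_path <- file.path(dir, ci$MarkerFile)
  mk <- parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
  onsets <- integer(0)
  for (m in mk) {
    spec <- strsplit(m, ",")[[1]]
    if (length(spec) >= 3 && grepl(marker, spec[2])) {
      onsets <- c(onsets, as.integer(spec[3]))
    }
  }
  assert_that(length(onsets) > 0, "no markers matching '%s' in %s", marker, vmrk_path)

  dt <- 1000 / sfreq
  rel <- seq(epoch_ms[1], epoch_ms[2] - dt, by = dt)
  off <- round(rel / dt)
  keep <- onsets[onsets + min(off) >= 1 & onsets + max(off) <= n_samp]
  assert_that(length(keep) > 0, "no marker leaves room for the epoch window")
  data <- array(0, dim = c(length(keep), n_ch, length(off)))
  for (i in seq_along(keep)) data[i, , ] <- cont[, keep[i] + off]
  if (is.null(conditions)) conditions <- rep("other", length(keep))
  epoch_set(data, sfreq, epoch_ms[1], chan, conditions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
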