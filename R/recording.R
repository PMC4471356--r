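#' Continuous multichannel EEG recording
#'
#' Container for a channels x samples signal matrix in microvolts,
#' its sampling rate, the electrode montage and the subset of
#' channels treated as EEG for referencing and detection.  All
#' arithmetic on the data is performed in double precision; single
#' precision round-off destroys the commutativity of the linear
#' operations the pipeline depends on, so non-double input is up-cast
#' with a warning.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz (finite, > 0).
#' @param montage an [montage()] whose labels match the data rows.
#' @param evaluation_channels labels of channels treated as EEG
#'   (default: all).  Mastoid/EOG channels should be excluded here.
#' @return object of class `eeg_recording`.
#' @export
recording <- function(data, fs, montage, evaluation_channels = NULL) {
  stopifnot(inherits(montage, "eeg_montage"))
  data <- as.matrix(data)
  if (storage.mode(data) != "double") {
    warning("recording data up-cast to double precision")
    storage.mode(data) <- "double"
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a finite positive sampling rate")
  if (nrow(data) != length(montage$labels))
    stop(sprintf("channel-count mismatch: %d data rows vs %d montage labels",
                 nrow(data), length(montage$labels)))
  if (nrow(data) < 2L)
    stop("a recording needs at least 2 channels")
  if (ncol(data) < fs)
    stop("a recording needs at least 1 s of data")
  rownames(data) <- montage$labels
  if (is.null(evaluation_channels)) evaluation_channels <- montage$labels
  evaluation_channels <- as.character(evaluation_channels)
  if (!all(evaluation_channels %in% montage$labels))
    stop("evaluation_channels must be montage labels")
  structure(list(data = data, fs = fs, montage = montage,
                 evaluation_channels = evaluation_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# replace the data matrix, keeping metadata
set_data <- function(rec, data) {
  rec$data <- data
  rownames(rec$data) <- rec$montage$labels
  rec
}

# index of evaluation channels within the montage order
eval_idx <- function(rec) match(rec$evaluation_channels, rec$montage$labels)

#' Partition a recording into non-overlapping windows
#'
#' Windows are contiguous, non-overlapping and exactly
#' `window_seconds * fs` samples long; a trailing partial window is
#' discarded (the windowed statistics are not defined for partial
#' windows).
#'
#' @param n_samples number of samples available.
#' @param fs sampling rate in Hz.
#' @param window_seconds window duration in seconds (default 1).
#' @return object of class `window_grid`: list with `window_seconds`,
#'   `size` (samples per window), `starts` (1-based start indices)
#'   and `count`.
#' @export
partition_windows <- function(n_samples, fs, window_seconds = 1) {
  size <- round(window_seconds * fs)
  if (size < 2L) stop("window too short: fewer than 2 samples")
  if (n_samples < size)
    stop(sprintf("recording shorter than one window (%d < %d samples)",
                 n_samples, size))
  count <- floor(n_samples / size)
  structure(list(window_seconds = window_seconds, size = as.integer(size),
                 starts = as.integer(seq(0L, count - 1L) * size + 1L),
                 count = as.integer(count)),
            class = "window_grid")
}

# channels x windows application of FUN over a window grid
window_apply <- function(x, grid, FUN) {
  vapply(seq_len(grid$count), function(w) {
    idx <- grid$starts[w]:(grid$starts[w] + grid$size - 1L)
    FUN(x[, idx, drop = FALSE])
  }, numeric(nrow(x)))
}
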