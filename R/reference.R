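# per-sample mean / median over a channel subset
subset_mean <- function(rec, chans) colMeans(rec$data[chans, , drop = FALSE])
subset_median <- function(rec, chans)
  .col_medians(rec$data[chans, , drop = FALSE])

# mean over reference channels of the recording with `bad` interpolated
interpolated_mean <- function(rec, bad, ref_chans) {
  if (length(bad) == 0L) return(subset_mean(rec, ref_chans))
  subset_mean(interpolate_channels(rec, bad), ref_chans)
}

#' Phase 1: estimate the true signal mean
#'
#' Iteratively estimates the per-sample mean the recording would have
#' if no channels were bad.  Starting from a robust initial estimate
#' (channel-wise median by default), bad channels are detected on the
#' referenced copy, accumulated, and the reference re-estimated as
#' the mean of the original signal with all accumulated bad channels
#' interpolated; the loop stops when the accumulated set stops
#' changing or the iteration cap is reached.
#'
#' @param rec an [recording()] (line-noise cleaned).
#' @param params a [reference_params()].
#' @param noisy a [noisy_params()].
#' @param seed RANSAC seed.
#' @return list with `reference_signal`, `bad_channels`,
#'   `iterations_used`, and `noisy_first` (the detection result of
#'   the first pass, i.e. the "original signal" statistics snapshot).
#' @export
phase1_estimate_true_mean <- function(rec, params = reference_params(),
                                      noisy = noisy_params(),
                                      seed = 4242L) {
  stopifnot(inherits(rec, "eeg_recording"))
  ref_chans <- params$reference_channels
  if (is.null(ref_chans)) ref_chans <- rec$evaluation_channels
  est0 <- switch(params$initial_estimate,
                 median = subset_median(rec, ref_chans),
                 mean = subset_mean(rec, ref_chans))
  temp <- set_data(rec, sweep(rec$data, 2L, est0))
  # fail fast when the recording is mostly unusable: the reference
  # would be meaningless long before detection could run
  nn <- detect_nan_nodata(rec, noisy)
  if (length(union(nn$nan, nn$no_data)) >
      params$bad_fraction_abort * length(ref_chans))
    stop(sprintf(paste0("robust reference aborted: %d of %d reference ",
                        "channels are unusable (NaN/no-data)"),
                 length(union(nn$nan, nn$no_data)), length(ref_chans)))
  bad <- character(0)
  noisy_first <- NULL
  iterations <- 0L
  repeat {
    nz <- find_noisy_channels(temp, noisy, seed = seed)
    if (is.null(noisy_first)) noisy_first <- nz
    new_bad <- union(bad, nz$bad_all)
    iterations <- iterations + 1L
    if (length(new_bad) > params$bad_fraction_abort * length(ref_chans))
      stop(sprintf(paste0("robust reference aborted: %d of %d reference ",
                          "channels accumulated as bad"),
                   length(new_bad), length(ref_chans)))
    if (setequal(new_bad, bad) || iterations >= params$max_iterations) {
      bad <- new_bad
      break
    }
    bad <- new_bad
    new_mean <- interpolated_mean(rec, bad, ref_chans)
    temp <- set_data(rec, sweep(rec$data, 2L, new_mean))
  }
  list(reference_signal = interpolated_mean(rec, bad, ref_chans),
       bad_channels = bad, iterations_used = iterations,
       noisy_first = noisy_first)
}

#' Phase 2: final detection, interpolation and re-reference
#'
#' Subtracts the phase-1 reference, re-detects bad channels from
#' scratch ("channel forgetting"), interpolates them (together with
#' any channels declared unusable in phase 1), subtracts the residual
#' per-sample channel mean and folds that correction back into the
#' stored reference signal, so the final output has (numerically)
#' zero mean over the reference channels at every sample.
#'
#' @param rec an [recording()] (line-noise cleaned, unreferenced).
#' @param reference_signal the phase-1 estimate.
#' @param params a [reference_params()].
#' @param noisy a [noisy_params()].
#' @param carry_unusable labels interpolated regardless of the
#'   phase-2 detection (unusable channels from phase 1).
#' @param seed RANSAC seed.
#' @return list with the referenced `recording`, updated
#'   `reference_signal`, `interpolated`, `still_bad`,
#'   `noisy_before_interp` and `noisy_final` snapshots.
#' @export
phase2_final_reference <- function(rec, reference_signal,
                                   params = reference_params(),
                                   noisy = noisy_params(),
                                   carry_unusable = character(0),
                                   seed = 4242L) {
  ref_chans <- params$reference_channels
  if (is.null(ref_chans)) ref_chans <- rec$evaluation_channels
  y <- set_data(rec, sweep(rec$data, 2L, reference_signal))
  noisy_before <- find_noisy_channels(y, noisy, seed = seed)
  interp <- union(noisy_before$bad_all, carry_unusable)
  y2 <- interpolate_channels(y, interp)
  correction <- subset_mean(y2, ref_chans)
  y2 <- set_data(y2, sweep(y2$data, 2L, correction))
  reference_signal <- reference_signal + correction
  noisy_final <- find_noisy_channels(y2, noisy, seed = seed)
  list(recording = y2, reference_signal = reference_signal,
       interpolated = interp,
       still_bad = noisy_final$bad_all,
       noisy_before_interp = noisy_before, noisy_final = noisy_final)
}

#' Robust average referencing
#'
#' Two-phase robust average referencing: phase 1 estimates the true
#' mean of the signal (iterative bad-channel interpolation), phase 2
#' detects bad channels relative to that mean, interpolates them and
#' re-references.  With no detectable bad channels the result equals
#' ordinary average referencing to double precision.  The stored
#' reference signal can be added back to every channel to recover the
#' unreferenced input on non-interpolated channels.
#'
#' @param rec an [recording()] (typically line-noise cleaned).
#' @param params a [reference_params()].
#' @param noisy a [noisy_params()].
#' @param seed RANSAC seed.
#' @return list with `recording` (referenced, interpolated) and
#'   `result`, a `reference_result`: `reference_signal`,
#'   `interpolated`, `still_bad`, `iterations_used`, and the three
#'   statistics snapshots `noisy_original`, `noisy_before_interp`,
#'   `noisy_final`.
#' @export
perform_reference <- function(rec, params = reference_params(),
                              noisy = noisy_params(),
                              seed = 4242L) {
  p1 <- phase1_estimate_true_mean(rec, params, noisy, seed)
  carry <- intersect(p1$noisy_first$unusable, p1$bad_channels)
  p2 <- phase2_final_reference(rec, p1$reference_signal, params,
                               noisy, carry_unusable = carry,
                               seed = seed)
  result <- structure(list(
    reference_signal = p2$reference_signal,
    interpolated = p2$interpolated,
    still_bad = p2$still_bad,
    iterations_used = p1$iterations_used,
    phase1_bad = p1$bad_channels,
    noisy_original = p1$noisy_first,
    noisy_before_interp = p2$noisy_before_interp,
    noisy_final = p2$noisy_final), class = "reference_result")
  list(recording = p2$recording, result = result)
}

#' @export
print.reference_result <- function(x, ...) {
  cat(sprintf(paste0("<reference_result> interpolated: %s | still bad: %s",
                     " | phase-1 iterations: %d\n"),
              if (length(x$interpolated)) paste(x$interpolated, collapse = ", ")
              else "none",
              if (length(x$still_bad)) paste(x$still_bad, collapse = ", ")
              else "none",
              x$iterations_used))
  invisible(x)
}
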