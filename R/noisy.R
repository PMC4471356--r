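# ---- robust statistics ---------------------------------------------

#' Robust standard deviation (0.7413 x IQR)
#'
#' Normal-consistent scale estimate immune to outliers: 0.7413 times
#' the interquartile range, with linear-interpolation quantiles
#' (R quantile type 7).
#'
#' @param x numeric vector with at least 2 values.
#' @return scalar.
#' @export
robust_sd <- function(x) {
  if (length(x) < 2L) stop("robust_sd needs at least 2 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  0.7413 * (q[2L] - q[1L])
}

#' Robust z-scores
#'
#' `(v - median(v)) / robust_sd(v)`: the mean is replaced by the
#' median and the standard deviation by the robust standard
#' deviation.  A degenerate spread (robust_sd of 0) yields all-zero
#' scores with attribute `degenerate = TRUE`.
#'
#' @param v numeric vector of per-channel scalars.
#' @return numeric vector of z-scores (attribute `degenerate`).
#' @export
robust_z <- function(v) {
  s <- robust_sd(v)
  if (!is.finite(s) || s == 0) {
    z <- rep(0, length(v))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (v - stats::median(v)) / s
  attr(z, "degenerate") <- FALSE
  z
}

# median absolute deviation without the normal-consistency constant
# (used only in ratios, where the constant cancels)
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

# ---- individual detectors ------------------------------------------

#' Detect NaN and no-data channels
#'
#' A channel is bad-by-NaN if it contains any non-finite sample, and
#' bad-by-NoData if its overall robust standard deviation is 0 or
#' more than `dropout_fraction` of its 1-s windows are exactly
#' constant.
#'
#' @param rec an [recording()].
#' @param params a [noisy_params()].
#' @return list of label vectors `nan` and `no_data`.
#' @export
detect_nan_nodata <- function(rec, params = noisy_params()) {
  labs <- rec$evaluation_channels
  x <- rec$data[labs, , drop = FALSE]
  bad_nan <- labs[!apply(is.finite(x), 1L, all)]
  usable <- setdiff(labs, bad_nan)
  grid <- partition_windows(ncol(x), rec$fs, 1)
  no_data <- character(0)
  for (ch in usable) {
    v <- x[ch, ]
    if (robust_sd(v) == 0) { no_data <- c(no_data, ch); next }
    const_frac <- mean(vapply(seq_len(grid$count), function(w) {
      idx <- grid$starts[w]:(grid$starts[w] + grid$size - 1L)
      max(v[idx]) == min(v[idx])
    }, logical(1)))
    if (const_frac > params$dropout_fraction) no_data <- c(no_data, ch)
  }
  list(nan = bad_nan, no_data = no_data)
}

#' Detect channels with deviant amplitude
#'
#' Robust z-score of each channel's robust standard deviation across
#' channels; |z| above the threshold (5 by default) flags the
#' channel.  Also returns per-window amplitude z-scores computed with
#' the overall robust median and robust standard deviation.
#'
#' @param rec an [recording()]; detection should run on a 1 Hz
#'   high-passed copy.
#' @param params a [noisy_params()].
#' @param channels channels to evaluate (default: evaluation set).
#' @return list with `bad`, `z` (named per-channel scores),
#'   `deviation_z` (channels x windows), `degenerate`.
#' @export
detect_deviation <- function(rec, params = noisy_params(),
                             channels = rec$evaluation_channels) {
  x <- rec$data[channels, , drop = FALSE]
  dev <- apply(x, 1L, robust_sd)
  z <- robust_z(dev)
  names(z) <- channels
  degenerate <- isTRUE(attr(z, "degenerate"))
  bad <- channels[abs(z) > params$robust_deviation_threshold]
  grid <- partition_windows(ncol(x), rec$fs, 1)
  wdev <- window_apply(x, grid, function(w) apply(w, 1L, robust_sd))
  med <- stats::median(dev)
  s <- robust_sd(dev)
  wz <- if (s > 0) (wdev - med) / s else wdev * 0
  rownames(wz) <- channels
  list(bad = if (degenerate) character(0) else bad, z = z,
       deviation_z = wz, degenerate = degenerate)
}

# Pearson correlation matrix with constant-column guard: any
# correlation involving a (numerically) constant window is 0
safe_cor <- function(m) {
  sds <- apply(m, 2L, stats::sd)
  ok <- is.finite(sds) & sds > 0
  r <- matrix(0, ncol(m), ncol(m))
  if (sum(ok) >= 2L)
    r[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  diag(r) <- 1
  r
}

#' Detect poorly correlated and dropout channels
#'
#' On the low-passed (50 Hz) signal, the per-window "maximum absolute
#' correlation" of a channel is the 98th percentile of the absolute
#' Pearson correlations with all other channels in 1-s windows.  A
#' channel is bad-by-correlation when that value falls below the
#' threshold (0.4) in strictly more than `bad_time_fraction` (1%) of
#' windows.  Windows where a channel is constant or numerically tiny
#' set dropout flags; a dropout-flag fraction above
#' `dropout_fraction` makes the channel bad-by-dropout.
#'
#' @param rec an [recording()] (1 Hz high-passed copy).
#' @param params a [noisy_params()].
#' @param channels channels to evaluate.
#' @param lowpassed optional pre-computed 50 Hz low-passed copy.
#' @return list with `bad_correlation`, `bad_dropout`,
#'   `max_correlation` (channels x windows), `dropout_flags`.
#' @export
detect_correlation_dropout <- function(rec, params = noisy_params(),
                                       channels = rec$evaluation_channels,
                                       lowpassed = NULL) {
  if (length(channels) < 2L) stop("correlation needs at least 2 channels")
  if (is.null(lowpassed))
    lowpassed <- fir_filter(rec, kind = "lowpass",
                            cutoff_hz = params$hf_split_hz)
  x <- lowpassed$data[channels, , drop = FALSE]
  grid <- partition_windows(ncol(x), rec$fs,
                            params$correlation_window_seconds)
  nc <- length(channels)
  maxcor <- matrix(NA_real_, nc, grid$count, dimnames = list(channels, NULL))
  dropout <- matrix(FALSE, nc, grid$count, dimnames = list(channels, NULL))
  pr <- params$correlation_percentile / 100
  tiny <- 1e-6                       # microvolt scale: numerically silent
  for (w in seq_len(grid$count)) {
    idx <- grid$starts[w]:(grid$starts[w] + grid$size - 1L)
    seg <- t(x[, idx, drop = FALSE])
    r <- abs(safe_cor(seg))
    diag(r) <- NA
    maxcor[, w] <- apply(r, 1L, function(v)
      stats::quantile(v, pr, names = FALSE, type = 7, na.rm = TRUE))
    rng <- apply(seg, 2L, function(v) max(v) - min(v))
    dropout[, w] <- rng <= tiny
  }
  frac_low <- rowMeans(maxcor < params$correlation_threshold)
  bad_corr <- channels[frac_low > params$bad_time_fraction]
  frac_drop <- rowMeans(dropout)
  bad_drop <- channels[frac_drop > params$dropout_fraction]
  list(bad_correlation = bad_corr, bad_dropout = bad_drop,
       max_correlation = maxcor, dropout_flags = dropout)
}

#' Detect channels with excessive high-frequency noise
#'
#' Noisiness is the ratio of the median absolute deviation of the
#' high-frequency component (signal minus 50 Hz low-pass) over the
#' low-frequency component, per channel; channels whose robust z
#' across channels exceeds the threshold (5) are bad-by-HF-noise.
#' Per-window noisiness z-scores (against the overall median/robust
#' SD) are retained for reporting.
#'
#' @param rec an [recording()] (1 Hz high-passed copy); errors when
#'   the sampling rate makes the 50 Hz split meaningless
#'   (fs <= 2 * `hf_split_hz`).
#' @param params a [noisy_params()].
#' @param channels channels to evaluate.
#' @param lowpassed optional pre-computed low-passed copy.
#' @return list with `bad`, `z`, `noise_z` (channels x windows),
#'   `noisiness`.
#' @export
detect_hf_noise <- function(rec, params = noisy_params(),
                            channels = rec$evaluation_channels,
                            lowpassed = NULL) {
  if (rec$fs <= 2 * params$hf_split_hz)
    stop(sprintf("fs = %g Hz leaves no high band above %g Hz",
                 rec$fs, params$hf_split_hz))
  if (is.null(lowpassed))
    lowpassed <- fir_filter(rec, kind = "lowpass",
                            cutoff_hz = params$hf_split_hz)
  lf <- lowpassed$data[channels, , drop = FALSE]
  hf <- rec$data[channels, , drop = FALSE] - lf
  ratio <- vapply(seq_along(channels), function(i) {
    d <- mad_raw(lf[i, ])
    if (d == 0) Inf else mad_raw(hf[i, ]) / d
  }, numeric(1))
  names(ratio) <- channels
  fin <- is.finite(ratio)
  z <- rep(Inf, length(ratio)); names(z) <- channels
  zr <- robust_z(ratio[fin])
  z[fin] <- zr
  bad <- channels[z > params$hf_noise_threshold]
  if (isTRUE(attr(zr, "degenerate"))) bad <- channels[!fin]
  grid <- partition_windows(ncol(lf), rec$fs, 1)
  wratio <- window_apply(hf, grid, function(w) {
    vapply(seq_len(nrow(w)), function(i) mad_raw(w[i, ]), numeric(1))
  }) / pmax(window_apply(lf, grid, function(w) {
    vapply(seq_len(nrow(w)), function(i) mad_raw(w[i, ]), numeric(1))
  }), .Machine$double.eps)
  med <- stats::median(ratio[fin])
  s <- robust_sd(ratio[fin])
  wz <- if (is.finite(s) && s > 0) (wratio - med) / s else wratio * 0
  rownames(wz) <- channels
  list(bad = bad, z = z, noise_z = wz, noisiness = ratio)
}

#' Detect unpredictable channels by RANSAC
#'
#' Each target channel is predicted from `ransac_sample_count` random
#' subsets of the good channels (each subset a fraction
#' `ransac_subset_fraction` of the good pool, excluding the target),
#' via the spherical-spline mapping; the per-sample median across
#' subsets is the RANSAC prediction.  A channel is bad-by-RANSAC when
#' the Pearson correlation between prediction and actual signal falls
#' below `ransac_correlation_threshold` in more than
#' `ransac_bad_fraction` of `ransac_window_seconds` windows.
#'
#' Predictions use the low-frequency (50 Hz low-passed) signal.  If
#' too few good channels remain to form subsets the detector returns
#' an empty set with `skipped = TRUE`.
#'
#' @param rec an [recording()] (1 Hz high-passed copy).
#' @param params a [noisy_params()].
#' @param exclude labels excluded from the predictor pool (unusable
#'   and already-bad channels).
#' @param channels target channels to evaluate.
#' @param lowpassed optional pre-computed low-passed copy.
#' @param seed integer seed for the subset draws.
#' @return list with `bad`, `ransac_correlation` (channels x
#'   windows), `bad_window_fraction`, `skipped`.
#' @export
detect_ransac <- function(rec, params = noisy_params(), exclude = character(0),
                          channels = rec$evaluation_channels,
                          lowpassed = NULL, seed = 4242L) {
  mont <- normalize_montage(rec$montage)
  if (is.null(lowpassed))
    lowpassed <- fir_filter(rec, kind = "lowpass",
                            cutoff_hz = params$hf_split_hz)
  good <- setdiff(rec$evaluation_channels, exclude)
  targets <- setdiff(channels, setdiff(exclude, good))
  grid <- partition_windows(ncol(rec$data), rec$fs,
                            params$ransac_window_seconds)
  empty <- list(bad = character(0),
                ransac_correlation =
                  matrix(NA_real_, length(channels), grid$count,
                         dimnames = list(channels, NULL)),
                bad_window_fraction =
                  stats::setNames(rep(NA_real_, length(channels)), channels),
                skipped = TRUE)
  subset_size <- ceiling(params$ransac_subset_fraction * length(good))
  if (length(good) - 1L < subset_size || length(good) < 4L || subset_size < 3L)
    return(empty)
  x <- lowpassed$data
  rc <- empty$ransac_correlation
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (tg in targets) {
    pool <- setdiff(good, tg)
    # one row of subset weights per draw (zeros off-subset), so all
    # predictions come from a single matrix product
    Wmat <- matrix(0, params$ransac_sample_count, length(pool))
    for (s in seq_len(params$ransac_sample_count)) {
      sub_i <- sample.int(length(pool), subset_size)
      model <- spline_model(mont$positions[pool[sub_i], , drop = FALSE],
                            mont$positions[tg, , drop = FALSE])
      Wmat[s, sub_i] <- build_interpolation_matrix(model)
    }
    preds <- Wmat %*% x[pool, , drop = FALSE]
    pred <- .col_medians(preds)
    actual <- x[tg, ]
    rc[tg, ] <- vapply(seq_len(grid$count), function(w) {
      idx <- grid$starts[w]:(grid$starts[w] + grid$size - 1L)
      sa <- stats::sd(actual[idx]); sp <- stats::sd(pred[idx])
      if (!is.finite(sa) || sa == 0 || !is.finite(sp) || sp == 0) 0
      else stats::cor(pred[idx], actual[idx])
    }, numeric(1))
  }
  frac <- rowMeans(rc < params$ransac_correlation_threshold)
  names(frac) <- rownames(rc)
  bad <- names(frac)[!is.na(frac) & frac > params$ransac_bad_fraction]
  list(bad = bad, ransac_correlation = rc, bad_window_fraction = frac,
       skipped = FALSE)
}

# ---- orchestration -------------------------------------------------

#' Find noisy channels
#'
#' Runs the full detection battery on a temporary 1 Hz high-passed
#' copy of the recording, in order: NaN/NoData, deviation,
#' correlation/dropout, high-frequency noisiness, low-SNR promotion
#' (channels failing both correlation and noisiness), then RANSAC
#' with the unusable and already-bad channels excluded from the
#' predictor pool.  Unusable channels (NaN, NoData, lowSNR) are
#' recorded once and excluded from all subsequent statistics.
#'
#' @param rec an [recording()].
#' @param params a [noisy_params()].
#' @param seed integer seed for RANSAC subset draws.
#' @param highpass apply the temporary 1 Hz high-pass before
#'   detection (default `TRUE`; set `FALSE` when the input is already
#'   high-passed).
#' @param detection_highpass_hz cutoff of the temporary high-pass.
#' @return object of class `noisy_channels`: list with `bad_by` (a
#'   list of label sets per category: nan, no_data, dropout,
#'   deviation, correlation, ransac, hf_noise, low_snr), `unusable`,
#'   `bad_all` (union of every category), `stats` (windowed arrays:
#'   `deviation_z`, `max_correlation`, `noise_z`,
#'   `ransac_correlation`, `dropout_flags`, per-channel scores), and
#'   `params`.
#' @export
find_noisy_channels <- function(rec, params = noisy_params(), seed = 4242L,
                                highpass = TRUE, detection_highpass_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(params, "noisy_params"))
  labs <- rec$evaluation_channels
  # NaN / NoData on the raw input (filtering would smear NaNs)
  nn <- detect_nan_nodata(rec, params)
  unusable <- union(nn$nan, nn$no_data)
  usable <- setdiff(labs, unusable)
  if (length(usable) < 2L)
    stop("fewer than 2 usable channels; cannot run detection")
  hp <- rec
  if (highpass) {
    hp$data[usable, ] <- apply_fir_matrix(
      rec$data[usable, , drop = FALSE],
      design_fir("highpass", detection_highpass_hz, rec$fs)$kernel)
  }
  lp <- hp
  lp$data[usable, ] <- apply_fir_matrix(
    hp$data[usable, , drop = FALSE],
    design_fir("lowpass", params$hf_split_hz, rec$fs)$kernel)
  dev <- detect_deviation(hp, params, usable)
  cd <- detect_correlation_dropout(hp, params, usable, lowpassed = lp)
  hf <- detect_hf_noise(hp, params, usable, lowpassed = lp)
  low_snr <- intersect(cd$bad_correlation, hf$bad)
  unusable <- union(unusable, low_snr)
  prior_bad <- Reduce(union, list(unusable, dev$bad, cd$bad_correlation,
                                  cd$bad_dropout, hf$bad))
  if (isTRUE(params$ransac_enabled)) {
    rs <- detect_ransac(hp, params, exclude = prior_bad,
                        channels = setdiff(usable, unusable),
                        lowpassed = lp, seed = seed)
  } else {
    grid <- partition_windows(ncol(rec$data), rec$fs,
                              params$ransac_window_seconds)
    rs <- list(bad = character(0),
               ransac_correlation = matrix(NA_real_, length(usable),
                                           grid$count,
                                           dimnames = list(usable, NULL)),
               bad_window_fraction = NULL, skipped = TRUE)
  }
  bad_by <- list(nan = nn$nan, no_data = nn$no_data,
                 dropout = cd$bad_dropout, deviation = dev$bad,
                 correlation = cd$bad_correlation, ransac = rs$bad,
                 hf_noise = hf$bad, low_snr = low_snr)
  full <- function(m) {         # expand stat arrays to all channels
    out <- matrix(NA_real_, length(labs), ncol(m),
                  dimnames = list(labs, NULL))
    out[rownames(m), ] <- m
    out
  }
  structure(list(
    bad_by = bad_by,
    unusable = unusable,
    bad_all = Reduce(union, bad_by),
    channels = labs,
    stats = list(deviation_z = full(dev$deviation_z),
                 max_correlation = full(cd$max_correlation),
                 noise_z = full(hf$noise_z),
                 ransac_correlation = full(rs$ransac_correlation),
                 dropout_flags = cd$dropout_flags,
                 deviation_channel_z = dev$z,
                 noisiness = hf$noisiness,
                 ransac_skipped = rs$skipped),
    params = params), class = "noisy_channels")
}

#' @export
print.noisy_channels <- function(x, ...) {
  n <- vapply(x$bad_by, length, 0L)
  cat(sprintf("<noisy_channels> %d/%d channels flagged\n",
              length(x$bad_all), length(x$channels)))
  for (k in names(n)) if (n[k] > 0L)
    cat(sprintf("  %-12s %s\n", k, paste(x$bad_by[[k]], collapse = ", ")))
  invisible(x)
}
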