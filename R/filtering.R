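#' Design a zero-phase windowed-sinc FIR filter
#'
#' Hamming-windowed sinc kernel, odd length, symmetric (linear phase;
#' applied centered so the net filter is zero-phase).  The cutoff is
#' the -6 dB (half-amplitude) point; the transition band is centered
#' on it.  High-pass kernels are obtained by spectral inversion of
#' the complementary low-pass.
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff_hz cutoff frequency (0 < cutoff < fs/2).
#' @param fs sampling rate (Hz).
#' @param transition_hz transition band width (Hz); the default is
#'   1 Hz for high-pass and 5 Hz for low-pass designs.
#' @return a `fir_spec`: list with `kernel` (odd-length numeric),
#'   `kind`, `cutoff_hz`, `transition_hz`, `fs`.
#' @export
design_fir <- function(kind = c("highpass", "lowpass"), cutoff_hz, fs,
                       transition_hz = NULL) {
  kind <- match.arg(kind)
  if (is.null(transition_hz))
    transition_hz <- if (kind == "highpass") 1 else 5
  stopifnot(transition_hz > 0)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie strictly between 0 and Nyquist")
  # Hamming window: transition ~ 3.3 / order * fs; keep order >= 3 fs / tw
  order <- ceiling(3.3 * fs / transition_hz)
  if (order %% 2L == 1L) order <- order + 1L
  L <- order + 1L                      # odd length
  m <- seq_len(L) - 1L - order / 2
  fc <- cutoff_hz / fs                 # cycles per sample
  h <- ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / order)
  h <- h * w
  h <- h / sum(h)                      # exact unit DC gain
  if (kind == "highpass") {
    h <- -h
    h[order / 2 + 1L] <- h[order / 2 + 1L] + 1
  }
  structure(list(kernel = h, kind = kind, cutoff_hz = cutoff_hz,
                 transition_hz = transition_hz, fs = fs),
            class = "fir_spec")
}

# zero-phase FFT convolution of each row with a symmetric kernel;
# edges are reflect-padded (mirror without repeating the edge sample)
apply_fir_matrix <- function(x, kernel) {
  L <- length(kernel)
  P <- (L - 1L) / 2L
  n <- ncol(x)
  if (n <= P + 1L)
    stop("signal too short for the designed filter kernel")
  left <- x[, (P + 1L):2L, drop = FALSE]
  right <- x[, (n - 1L):(n - P), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  n2 <- stats::nextn(np + L - 1L, 2L)
  H <- stats::fft(c(kernel, numeric(n2 - L)))
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(xp[i, ], numeric(n2 - np)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / n2
    out[i, ] <- y[(2L * P + 1L):(2L * P + n)]
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Apply a zero-phase FIR filter to a recording
#'
#' @param rec an [recording()].
#' @param spec a [design_fir()] spec, or `NULL` to design one from
#'   `kind` and `cutoff_hz` at the recording's sampling rate.
#' @param kind,cutoff_hz,transition_hz used when `spec` is `NULL`.
#' @return the filtered recording (no group delay).
#' @export
fir_filter <- function(rec, spec = NULL, kind = "highpass", cutoff_hz = 1,
                       transition_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(spec))
    spec <- design_fir(kind, cutoff_hz, rec$fs, transition_hz)
  if (!isTRUE(all.equal(spec$fs, rec$fs)))
    stop("filter was designed for a different sampling rate")
  set_data(rec, apply_fir_matrix(rec$data, spec$kernel))
}

#' Fit the best linear trend of a channel
#'
#' Least-squares line over sample index, plus the Pearson correlation
#' of the channel with its own fitted line (a drift severity
#' diagnostic: near +/-1 for strongly drifting channels, near 0 for
#' stationary ones).
#'
#' @param channel numeric sample vector.
#' @return list with `slope` (per sample), `intercept`, `correlation`
#'   and `degenerate` (`TRUE` when the channel or fit is constant and
#'   the correlation is reported as 0).
#' @export
fit_linear_trend <- function(channel) {
  n <- length(channel)
  stopifnot(n >= 2L)
  t <- seq_len(n)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  slope <- sum(tc * channel) / denom
  intercept <- mean(channel) - slope * mean(t)
  fitted <- intercept + slope * t
  sdc <- stats::sd(channel)
  sdf <- stats::sd(fitted)
  degenerate <- !is.finite(sdc) || sdc == 0 || !is.finite(sdf) ||
    sdf < 1e-14 * max(sdc, abs(mean(channel)), 1)
  corr <- if (degenerate) 0 else stats::cor(channel, fitted)
  list(slope = slope, intercept = intercept, correlation = corr,
       degenerate = degenerate)
}

#' Remove the global best-fit linear trend from every channel
#'
#' After removal each channel has zero best-fit slope.  Idempotent.
#'
#' @param rec an [recording()].
#' @return the detrended recording.
#' @export
remove_linear_trend <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  t <- seq_len(n)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  slopes <- as.vector(rec$data %*% tc) / denom
  # remove the sloped part only; the channel mean is preserved
  set_data(rec, rec$data - outer(slopes, tc))
}
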