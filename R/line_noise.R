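# ---- Slepian tapers ------------------------------------------------

# memo cache for dpss results (keyed by N/nw/K)
.taper_cache <- new.env(parent = emptyenv())

# discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Slepian's tridiagonal matrix commutes with the
# concentration operator, so its top eigenvectors are the tapers)
dpss <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- get0(key, envir = .taper_cache)
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off_v <- (t * (n - t) / 2)[2:n]
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_v
  A[cbind(seq_len(n - 1L), seq(2L, n))] <- off_v
  A[cbind(seq(2L, n), seq_len(n - 1L))] <- off_v
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric
  # tapers positive initial slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[2L, j] - v[1L, j] < 0) v[, j] <- -v[, j]
  }
  assign(key, v, envir = .taper_cache)
  v
}

#' Build the Slepian taper set for line-noise estimation
#'
#' For a window of `window_seconds` (W) containing `n_samples` (N)
#' points and a taper bandwidth of `taper_bandwidth_hz` (TBW), the
#' tapers are dpss(N, TBW*W/2, TBW*W - 1): time-bandwidth product
#' nw = TBW*W/2 and K = TBW*W - 1 orthonormal sequences (7 tapers at
#' the defaults W = 4 s, TBW = 2 Hz).
#'
#' @param n_samples window length in samples.
#' @param taper_bandwidth_hz taper bandwidth TBW (Hz).
#' @param window_seconds window duration W (s).
#' @return a `taper_set`: list with `tapers` (K x N matrix), `k`,
#'   `nw`, `n`.
#' @export
make_tapers <- function(n_samples, taper_bandwidth_hz = 2,
                        window_seconds = 4) {
  nw <- taper_bandwidth_hz * window_seconds / 2
  k <- round(taper_bandwidth_hz * window_seconds - 1)
  if (k < 2L) stop("taper count < 2: the F-test is undefined")
  if (n_samples < 2L * k) stop("window too short for the taper count")
  v <- dpss(as.integer(n_samples), nw, as.integer(k))
  structure(list(tapers = t(v), k = as.integer(k), nw = nw,
                 n = as.integer(n_samples)),
            class = "taper_set")
}

# ---- Thomson harmonic F-test ---------------------------------------

# eigencoefficients of a single window at one frequency
eigencoef <- function(window, tapers, f, fs) {
  t <- (seq_len(tapers$n) - 1) / fs
  e <- exp(-2i * pi * f * t)
  as.vector(tapers$tapers %*% (window * e))
}

# core F computation from eigencoefficients y (K-vector, complex) and
# taper DC sums H
fstat_from_coef <- function(y, H) {
  sH2 <- sum(H^2)
  mu <- sum(y * H) / sH2
  resid <- y - mu * H
  k <- length(y)
  num <- (k - 1) * Mod(mu)^2 * sH2
  den <- sum(Mod(resid)^2)
  f <- if (den <= 0) Inf else num / den
  list(mu = mu, f = f)
}

#' Thomson harmonic F-test for a sinusoid at a fixed frequency
#'
#' Fits the complex amplitude of a deterministic sinusoid at `f` by
#' tapered frequency-domain regression and tests whether it is
#' significantly non-zero against the locally white background.  The
#' F statistic has (2, 2K-2) degrees of freedom under the null.
#'
#' @param window numeric sample vector (length must match the tapers).
#' @param tapers a [make_tapers()] set.
#' @param f frequency in Hz (must be below Nyquist).
#' @param fs sampling rate in Hz.
#' @return a `harmonic_fit`: list with `frequency_hz`, `mu` (complex
#'   regression coefficient), `amplitude` (real sinusoid amplitude,
#'   2|mu|), `phase`, `f_statistic`, `p_value`, `df`.
#' @export
harmonic_f_test <- function(window, tapers, f, fs) {
  stopifnot(inherits(tapers, "taper_set"), length(window) == tapers$n)
  if (f >= fs / 2) stop("frequency at or above Nyquist")
  H <- rowSums(tapers$tapers)
  y <- eigencoef(window, tapers, f, fs)
  r <- fstat_from_coef(y, H)
  k <- tapers$k
  p <- stats::pf(r$f, 2, 2 * k - 2, lower.tail = FALSE)
  structure(list(frequency_hz = f, mu = r$mu, amplitude = 2 * Mod(r$mu),
                 phase = Arg(r$mu), f_statistic = r$f, p_value = p,
                 df = c(2, 2 * k - 2)),
            class = "harmonic_fit")
}

# scan grid around f0: FFT bins of the 4x zero-padded window
scan_grid <- function(f0, half_width, fs, n) {
  res <- fs / (4 * n)
  if (half_width <= 0) return(f0)
  k <- floor(half_width / res)
  f <- f0 + res * seq(-k, k)
  f[f > 0 & f < fs / 2]
}

#' Scan for the line frequency maximizing the F statistic
#'
#' Evaluates the harmonic F-test on a grid of frequencies in
#' `[f0 - half_width, f0 + half_width]` (grid resolution fs/(4N), the
#' FFT bin spacing of the 4x zero-padded window) and returns the fit
#' at the maximizing frequency.
#'
#' @inheritParams harmonic_f_test
#' @param f0 nominal line frequency (Hz).
#' @param half_width scan half-width (Hz); 0 degenerates to a single
#'   test at `f0`.
#' @return a `harmonic_fit` (see [harmonic_f_test()]).
#' @export
scan_frequency <- function(window, tapers, f0, half_width, fs) {
  grid <- scan_grid(f0, half_width, fs, tapers$n)
  if (length(grid) == 0L) stop("empty scan range")
  H <- rowSums(tapers$tapers)
  t <- (seq_len(tapers$n) - 1) / fs
  tw <- tapers$tapers * rep(window, each = tapers$k)
  best <- NULL
  for (f in grid) {
    y <- as.vector(tw %*% exp(-2i * pi * f * t))
    r <- fstat_from_coef(y, H)
    if (is.null(best) || r$f > best$f_statistic)
      best <- list(frequency_hz = f, mu = r$mu, f_statistic = r$f)
  }
  k <- tapers$k
  p <- stats::pf(best$f_statistic, 2, 2 * k - 2, lower.tail = FALSE)
  structure(list(frequency_hz = best$frequency_hz, mu = best$mu,
                 amplitude = 2 * Mod(best$mu), phase = Arg(best$mu),
                 f_statistic = best$f_statistic, p_value = p,
                 df = c(2, 2 * k - 2)),
            class = "harmonic_fit")
}

# ---- sliding-window removal ----------------------------------------

# window start indices: slide by `slide`, and append a final window
# ending exactly at n so trailing samples are covered (trailing
# chunks shorter than one window are merged into the last window)
line_window_starts <- function(n, nwin, slide) {
  starts <- seq(1L, n - nwin + 1L, by = slide)
  if (utils::tail(starts, 1L) + nwin - 1L < n)
    starts <- c(starts, n - nwin + 1L)
  starts
}

# batched tapered transforms: F statistics and mu for every
# (window, frequency) pair of one channel.  Returns list(fstat, mu)
# with dim nstarts x nfreq.
batch_harmonic <- function(x, starts, tapers, freqs, fs) {
  nwin <- tapers$n
  k <- tapers$k
  nf <- length(freqs)
  ns <- length(starts)
  idx <- outer(seq_len(nwin) - 1L, starts, `+`)      # nwin x ns
  Wm <- matrix(x[idx], nrow = nwin)                  # nwin x ns
  t <- (seq_len(nwin) - 1) / fs
  ph <- outer(t, freqs) * (2 * pi)                   # nwin x nf
  Cs <- cos(ph); Sn <- sin(ph)
  H <- rowSums(tapers$tapers)
  sH2 <- sum(H^2)
  num_r <- matrix(0, ns, nf); num_i <- matrix(0, ns, nf)
  den <- matrix(0, ns, nf)
  yr <- array(0, c(ns, nf, k)); yi <- array(0, c(ns, nf, k))
  for (j in seq_len(k)) {
    Tw <- Wm * tapers$tapers[j, ]                    # taper * window
    re <- crossprod(Tw, Cs)                          # ns x nf
    im <- -crossprod(Tw, Sn)
    yr[, , j] <- re; yi[, , j] <- im
    num_r <- num_r + re * H[j]
    num_i <- num_i + im * H[j]
  }
  mur <- num_r / sH2; mui <- num_i / sH2
  for (j in seq_len(k))
    den <- den + (yr[, , j] - mur * H[j])^2 + (yi[, , j] - mui * H[j])^2
  fstat <- (k - 1) * (mur^2 + mui^2) * sH2 / den
  fstat[den <= 0] <- Inf
  list(fstat = fstat, mur = mur, mui = mui)
}

# reconstruct + stitch the fitted sinusoids of one channel for one
# frequency; sig rows: start, freq, mur, mui.  Returns the estimated
# noise waveform (zeros where nothing was significant).
stitch_channel <- function(n, nwin, fits, fs, tau) {
  noise <- numeric(n)
  filled_to <- 0L                                    # last sample written
  if (nrow(fits) == 0L) return(noise)
  for (r in seq_len(nrow(fits))) {
    s <- fits[r, 1L]
    f <- fits[r, 2L]
    mu <- complex(real = fits[r, 3L], imaginary = fits[r, 4L])
    t <- (s - 1 + seq_len(nwin) - 1) / fs            # global time axis
    seg <- 2 * Re(mu * exp(2i * pi * f * t))
    e <- s + nwin - 1L
    ov_end <- min(filled_to, e)
    if (ov_end >= s) {                               # blend the overlap
      LL <- ov_end - s + 1L
      off <- seq_len(LL) - (LL + 1) / 2
      w <- 1 / (1 + exp(-off / tau))
      idx <- s:ov_end
      noise[idx] <- (1 - w) * noise[idx] + w * seg[seq_len(LL)]
      if (e > ov_end) noise[(ov_end + 1L):e] <- seg[(LL + 1L):nwin]
    } else {
      noise[s:e] <- seg
    }
    filled_to <- max(filled_to, e)
  }
  noise
}

#' Remove line noise from an already high-passed recording
#'
#' Multitaper harmonic-regression removal: per channel, 4-s windows
#' sliding by 1 s are scanned for the frequency (within +/- 2 Hz of
#' each candidate) maximizing the Thomson F statistic; where the
#' fitted sinusoid is significant (p < 0.01) it is reconstructed in
#' the time domain, stitched across overlapping windows with
#' sigmoidal weights (parameter `tau`, in samples), and subtracted.
#' The process repeats until the candidate amplitude is no longer
#' significantly different from the background (a frequency is
#' dropped once insignificant in at least 99% of windows, or when an
#' iteration makes no progress) or `max_iterations` is reached.
#'
#' The caller is responsible for the input being free of large
#' low-frequency trends (high-passed or detrended); see
#' [clean_line_noise()] for the trend-safe entry point.
#'
#' @param rec an [recording()], already high-passed/detrended.
#' @param params a [line_noise_params()].
#' @return list with `clean` (recording) and `noise` (recording);
#'   `clean$data + noise$data` reconstructs the input exactly.
#' @export
remove_line_noise_filtered <- function(rec, params = line_noise_params()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(params, "line_noise_params"))
  fs <- rec$fs
  n <- ncol(rec$data)
  nwin <- round(params$window_seconds * fs)
  if (n < nwin) stop("recording shorter than one line-noise window")
  slide <- round(params$slide_seconds * fs)
  freqs0 <- params$line_frequencies_hz
  if (is.null(freqs0)) freqs0 <- seq(60, fs / 2 - 1e-9, by = 60)
  freqs0 <- freqs0[freqs0 > 0 & freqs0 < fs / 2]
  if (length(freqs0) == 0L)
    return(list(clean = rec, noise = set_data(rec, rec$data * 0)))
  tapers <- make_tapers(nwin, params$taper_bandwidth_hz,
                        params$window_seconds)
  starts <- line_window_starts(n, nwin, slide)
  nstarts <- length(starts)
  # effective number of independent frequencies in the scan range
  # (Rayleigh-resolution bins), for the optional Sidak correction
  n_indep <- max(1, round(2 * params$f_scan_bandwidth_hz / (fs / nwin)))
  k <- tapers$k
  fcrit_p <- function(fst) {
    p <- stats::pf(fst, 2, 2 * k - 2, lower.tail = FALSE)
    if (params$scan_correction && params$f_scan_bandwidth_hz > 0)
      p <- 1 - (1 - p)^n_indep
    p
  }
  noise_total <- matrix(0, nrow(rec$data), n)
  x <- rec$data
  for (ch in seq_len(nrow(x))) {
    active <- rep(TRUE, length(freqs0))
    prev_sig <- rep(Inf, length(freqs0))
    xi <- x[ch, ]
    for (iter in seq_len(params$max_iterations)) {
      if (!any(active)) break
      ch_noise <- numeric(n)
      for (fi in which(active)) {
        grid <- scan_grid(freqs0[fi], params$f_scan_bandwidth_hz, fs, nwin)
        bh <- batch_harmonic(xi, starts, tapers, grid, fs)
        best <- max.col(bh$fstat, ties.method = "first")
        rows <- seq_len(nstarts)
        fmax <- bh$fstat[cbind(rows, best)]
        pvals <- fcrit_p(fmax)
        sig <- which(pvals < params$p_threshold)
        nsig <- length(sig)
        if (nsig / nstarts <= 1 - 0.99 || nsig >= prev_sig[fi]) {
          active[fi] <- FALSE
          if (nsig == 0L) next
        }
        prev_sig[fi] <- nsig
        if (nsig == 0L) next
        fits <- cbind(starts[sig], grid[best[sig]],
                      bh$mur[cbind(sig, best[sig])],
                      bh$mui[cbind(sig, best[sig])])
        ch_noise <- ch_noise +
          stitch_channel(n, nwin, fits, fs, params$tau)
      }
      xi <- xi - ch_noise
      noise_total[ch, ] <- noise_total[ch, ] + ch_noise
      if (!any(active)) break
    }
  }
  clean <- set_data(rec, rec$data - noise_total)
  noise <- set_data(rec, noise_total)
  list(clean = clean, noise = noise)
}

#' Remove line noise without committing to a filtering strategy
#'
#' Capture-and-subtract cleaning: the signal is temporarily
#' high-passed at `detection_highpass_hz` (1 Hz default), line noise
#' is estimated and captured on that copy, and the captured noise is
#' subtracted from the ORIGINAL unfiltered signal.  Drift and other
#' low-frequency content are preserved in the output, while a later
#' high-pass of the output shows the line peak removed as though
#' filtering had preceded removal.
#'
#' @param rec an [recording()] (raw; may drift).
#' @param params a [line_noise_params()].
#' @return list with `clean` (unfiltered recording minus captured
#'   noise) and `noise` (the captured line-noise recording).
#' @export
clean_line_noise <- function(rec, params = line_noise_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  hp <- fir_filter(rec, kind = "highpass",
                   cutoff_hz = params$detection_highpass_hz)
  res <- remove_line_noise_filtered(hp, params)
  list(clean = set_data(rec, rec$data - res$noise$data),
       noise = res$noise)
}
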