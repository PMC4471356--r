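# shared fixtures and independent oracles for the test suite

# sort-based type-7 quantile, written independently of stats::quantile
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small montage: a subset of the standard 32-cap
small_montage <- function(n = 8L) {
  m <- montage_std32()
  keep <- seq(1L, length(m$labels), length.out = n)
  montage(m$labels[keep], m$positions[keep, , drop = FALSE])
}

# quick multichannel recording: two orthogonal components mixed
# around a ring (zero-mean weights), so channels stay correlated
# with their ring neighbors even after channel-mean subtraction
toy_recording <- function(n_sec = 20, fs = 200, nch = 8, seed = 1) {
  set.seed(seed)
  n <- n_sec * fs
  t <- (0:(n - 1)) / fs
  b1 <- sin(2 * pi * 7 * t) * 20 + sin(2 * pi * 3 * t + 1) * 10
  b2 <- sin(2 * pi * 5 * t + 0.7) * 20 + sin(2 * pi * 11 * t) * 10
  theta <- 2 * pi * (seq_len(nch) - 1) / nch
  data <- outer(cos(theta), rep(1, n)) * rep(b1, each = nch) +
    outer(sin(theta), rep(1, n)) * rep(b2, each = nch)
  dim(data) <- c(nch, n)
  data <- data + matrix(rnorm(nch * n, 0, 2), nch)
  recording(data, fs, small_montage(nch))
}

# independent EDF writer (16-bit), coded from the format description
# and deliberately separate from the package reader
write_edf_fixture <- function(path, data, fs, labels,
                              phys_range = c(-1000, 1000)) {
  nch <- nrow(data); n <- ncol(data)
  record_sec <- 1
  nsamp <- fs * record_sec
  n_rec <- n %/% nsamp
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    writeChar(formatC(s, width = -w), con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (1 + nch), 8); pad("", 44); pad(n_rec, 8); pad(record_sec, 8)
  pad(nch, 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(nch)) pad("test", 80)
  for (i in seq_len(nch)) pad("uV", 8)
  for (i in seq_len(nch)) pad(phys_range[1], 8)
  for (i in seq_len(nch)) pad(phys_range[2], 8)
  for (i in seq_len(nch)) pad(-32768, 8)
  for (i in seq_len(nch)) pad(32767, 8)
  for (i in seq_len(nch)) pad("", 80)
  for (i in seq_len(nch)) pad(nsamp, 8)
  for (i in seq_len(nch)) pad("", 32)
  scale <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  dig <- round((data - phys_range[1]) / scale + (-32768))
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * nsamp + 1):(r * nsamp)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}

# single-sided periodogram in dB; returns list(f, p)
periodogram_db <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  keep <- f <= fs / 2
  list(f = f[keep], p = 10 * log10(P[keep] + 1e-300))
}

# smooth spherical field from low-degree Legendre polynomials of
# random axes (degree <= 3 harmonic content)
harmonic_field <- function(positions, seed = 1) {
  set.seed(seed)
  f <- numeric(nrow(positions))
  for (deg in 1:3) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    x <- as.vector(positions %*% a)
    f <- f + switch(deg, x, 0.5 * (3 * x^2 - 1), 0.5 * (5 * x^3 - 3 * x))
  }
  f
}
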