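fs <- 200

test_that("robust_sd matches the quantile oracle", {
  expect_equal(robust_sd(rep(3, 10)), 0)
  x <- 1:100
  expect_equal(robust_sd(x),
               0.7413 * (quantile7_oracle(x, 0.75) -
                           quantile7_oracle(x, 0.25)),
               tolerance = 1e-12)
  set.seed(1)
  z <- rnorm(1e5)
  expect_lt(abs(robust_sd(z) - 1), 0.02)   # IQR of N(0,1) = 1.349
  expect_error(robust_sd(1), "at least 2")
})

test_that("robust_z centers at the median and flags degeneracy", {
  v <- c(1, 2, 3, 4, 5)
  z <- robust_z(v)
  expect_equal(z[3], 0)
  v2 <- c(1, 2, 3, 4, 101)
  z2 <- robust_z(v2)
  expect_equal(unname(z2[5]), (101 - 3) / robust_sd(v2), tolerance = 1e-12)
  expect_gt(z2[5], 5)
  zd <- robust_z(rep(7, 6))
  expect_true(attr(zd, "degenerate"))
  expect_equal(as.vector(zd), rep(0, 6))
})

test_that("NaN and no-data channels are caught", {
  rec <- toy_recording(n_sec = 5, nch = 6, seed = 2)
  rec$data[2, 100] <- NaN
  rec$data[4, ] <- 0
  nn <- detect_nan_nodata(rec)
  expect_identical(nn$nan, rec$montage$labels[2])
  expect_identical(nn$no_data, rec$montage$labels[4])
  clean <- toy_recording(n_sec = 5, nch = 6, seed = 3)
  nn2 <- detect_nan_nodata(clean)
  expect_length(nn2$nan, 0)
  expect_length(nn2$no_data, 0)
})

test_that("deviation criterion flags amplitude outliers numerically", {
  set.seed(4)
  n <- 10 * fs
  m <- montage_std32()
  data <- matrix(rnorm(32 * n, 0, 10), 32)
  data[13, ] <- rnorm(n, 0, 80)
  rec <- recording(data, fs, m)
  d <- detect_deviation(rec)
  expect_identical(d$bad, m$labels[13])
  expect_gt(abs(d$z[13]), 5)
  expect_equal(dim(d$deviation_z), c(32L, 10L))
  # identical-variance channels: empty
  d2 <- detect_deviation(recording(matrix(rnorm(32 * n, 0, 10), 32), fs, m))
  expect_length(d2$bad, 0)
  expect_equal(noisy_params()$robust_deviation_threshold, 5)
})

test_that("correlation criterion uses a strict window-fraction rule", {
  set.seed(5)
  n_win <- 100
  n <- n_win * fs
  t <- (0:(n - 1)) / fs
  base <- sin(2 * pi * 8 * t) * 20
  m <- small_montage(6)
  data <- t(vapply(1:6, function(i) base + rnorm(n, 0, 0.5), numeric(n)))
  kill <- function(d, ch, wins) {
    for (w in wins) d[ch, ((w - 1) * fs + 1):(w * fs)] <- rnorm(fs, 0, 20)
    d
  }
  # exactly 1% of windows bad -> NOT flagged (strict >)
  d1 <- kill(data, 3, 1)
  r1 <- detect_correlation_dropout(recording(d1, fs, m))
  expect_false(m$labels[3] %in% r1$bad_correlation)
  # 2% of windows bad -> flagged
  d2 <- kill(data, 3, c(1, 50))
  r2 <- detect_correlation_dropout(recording(d2, fs, m))
  expect_true(m$labels[3] %in% r2$bad_correlation)
  expect_true(all(r2$max_correlation >= 0 & r2$max_correlation <= 1))
})

test_that("temporally shuffled channels fail correlation", {
  rec <- toy_recording(n_sec = 30, nch = 8, seed = 6)
  rec$data[5, ] <- sample(rec$data[5, ])
  r <- detect_correlation_dropout(rec)
  expect_true(rec$montage$labels[5] %in% r$bad_correlation)
  # the ring neighbors of every intact channel stay well correlated
  expect_gt(min(rowMeans(r$max_correlation[-5, ])), 0.6)
})

test_that("dropout windows mark intermittently flat channels", {
  rec <- toy_recording(n_sec = 50, nch = 6, seed = 7)
  rec$data[2, 1:(5 * fs)] <- 0.123        # 10% of windows flat
  r <- detect_correlation_dropout(rec)
  expect_true(rec$montage$labels[2] %in% r$bad_dropout)
  expect_gte(sum(r$dropout_flags[2, ]), 4)
})

test_that("high-frequency noisiness flags numerically", {
  set.seed(8)
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  m <- montage_std32()
  lowf <- sin(2 * pi * 6 * t) * 15
  data <- t(vapply(1:32, function(i) lowf + rnorm(n, 0, 1), numeric(n)))
  hfn <- sin(2 * pi * 70 * t)
  data[20, ] <- data[20, ] + 8 * hfn * rnorm(n, 1, 0.3)
  rec <- recording(data, fs, m)
  h <- detect_hf_noise(rec)
  expect_true(m$labels[20] %in% h$bad)
  # spectrally identical channels: empty
  h2 <- detect_hf_noise(recording(
    t(vapply(1:32, function(i) lowf + rnorm(n, 0, 1), numeric(n))), fs, m))
  expect_length(h2$bad, 0)
  expect_error(detect_hf_noise(recording(matrix(rnorm(32 * 300), 32), 90, m)),
               "no high band")
})

test_that("RANSAC flags the spline-unpredictable channel only", {
  set.seed(9)
  n <- 40 * fs
  m <- montage_std32()
  mont <- normalize_montage(m)
  # smooth spatial field: every channel spline-predictable
  f1 <- harmonic_field(mont$positions, seed = 1)
  f2 <- harmonic_field(mont$positions, seed = 2)
  s0 <- eegpipe:::pink_series(n, fs) * 20      # common component so no
  s1 <- eegpipe:::pink_series(n, fs) * 20      # channel is signal-free
  s2 <- eegpipe:::pink_series(n, fs) * 20
  data <- rep(1, 32) %o% s0 +
    outer(f1, rep(1, n)) * rep(s1, each = 32) +
    outer(f2, rep(1, n)) * rep(s2, each = 32)
  dim(data) <- c(32L, n)
  data <- data + matrix(rnorm(32 * n, 0, 0.5), 32)
  data[16, ] <- rnorm(n, 0, sd(data[16, ]))     # independent noise at Cz
  rec <- recording(data, fs, m)
  r <- detect_ransac(rec, seed = 11)
  expect_true(m$labels[16] %in% r$bad)
  expect_length(setdiff(r$bad, m$labels[16]), 0)
  expect_false(r$skipped)
  # too few predictors: skipped with flag
  r2 <- detect_ransac(rec, exclude = m$labels[1:30], seed = 11)
  expect_true(r2$skipped)
  expect_length(r2$bad, 0)
})

test_that("find_noisy_channels promotes low-SNR and is deterministic", {
  rec <- toy_recording(n_sec = 30, nch = 8, seed = 10)
  # one-tenth-amplitude channel with unchanged amplifier noise: fails
  # correlation and noisiness together -> low SNR, unusable
  set.seed(10)
  rec$data[4, ] <- 0.02 * rec$data[4, ] + rnorm(ncol(rec$data), 0, 2)
  nz <- find_noisy_channels(rec, seed = 12)
  lab <- rec$montage$labels[4]
  expect_true(lab %in% nz$bad_by$correlation)
  expect_true(lab %in% nz$bad_by$hf_noise)
  expect_true(lab %in% nz$bad_by$low_snr)
  expect_true(lab %in% nz$unusable)
  # determinism given the seed
  nz2 <- find_noisy_channels(rec, seed = 12)
  expect_identical(nz$bad_by, nz2$bad_by)
  expect_identical(nz$stats$ransac_correlation, nz2$stats$ransac_correlation)
  # windowed arrays share the channel dimension
  expect_equal(nrow(nz$stats$deviation_z), 8L)
  expect_equal(nrow(nz$stats$max_correlation), 8L)
  expect_equal(nrow(nz$stats$noise_z), 8L)
})

test_that("category sets stay inside the evaluation set; clean is clean", {
  rec <- toy_recording(n_sec = 20, nch = 8, seed = 11)
  nz <- find_noisy_channels(rec, seed = 13)
  expect_length(nz$bad_all, 0)
  for (b in nz$bad_by) expect_true(all(b %in% rec$evaluation_channels))
})

test_that("detection is monotone in the injected noise amplitude", {
  sp <- synthetic_spec(duration_seconds = 60, seed = 21)
  rec <- generate_clean(sp)
  cl <- fir_filter(rec, kind = "highpass", cutoff_hz = 1)
  lab <- "P3"
  set.seed(14)
  noise <- rnorm(ncol(cl$data))
  for (mult in c(4, 8, 16)) {
    inj <- cl
    inj$data[lab, ] <- inj$data[lab, ] +
      noise * mult * sd(cl$data[lab, ])
    nz <- find_noisy_channels(inj, seed = 15, highpass = FALSE)
    expect_true(lab %in% nz$bad_all,
                label = sprintf("gaussian x%d detected", mult))
  }
})
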