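# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# one 1/f ("pink") unit-variance series of length n at rate fs,
# generated by spectral shaping with a 1 Hz knee.  Above `roll_hz`
# the spectrum rolls off smoothly (cortical EEG falls much faster
# than 1/f at high frequencies), so the high band is left to the
# amplifier noise floor.
pink_series <- function(n, fs, roll_hz = 40) {
  n2 <- stats::nextn(n, 2L)
  f <- seq(0, fs / 2, length.out = n2 / 2 + 1L)
  amp <- 1 / sqrt(pmax(f, 1))
  hi <- f > roll_hz
  amp[hi] <- amp[hi] * exp(-((f[hi] - roll_hz) / 3)^2)
  amp[1L] <- 0
  half <- (stats::rnorm(n2 / 2 + 1L) + 1i * stats::rnorm(n2 / 2 + 1L)) * amp
  half[1L] <- 0; half[n2 / 2 + 1L] <- Re(half[n2 / 2 + 1L])
  spec <- c(half, Conj(half[(n2 / 2):2]))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

#' Synthetic EEG specification
#'
#' The stated world of the generator: a 32-channel, 5-minute, 200 Hz
#' session.  Clean channels sample a spatially smooth random field:
#' many dipolar 1/f sources (random orientations, broad
#' volume-conduction kernels) are mixed by distance decay, partially
#' normalized so channel gains vary moderately (log-normal), with
#' per-channel linear drift drawn from `drift_slope_range`
#' (microvolts per sample), a 60 Hz line component with slow shared
#' amplitude and phase wander, and a white amplifier noise floor of
#' about `noise_floor` microvolts that does not scale with the scalp
#' signal.  See the methods vignette for what the generator emulates
#' and what it deliberately does not.
#'
#' @param n_channels number of channels (must match the montage).
#' @param duration_seconds session length (s).
#' @param fs sampling rate (Hz).
#' @param montage an [montage()]; default [montage_std32()].
#' @param source_count number of 1/f sources.
#' @param source_width Gaussian spatial kernel width (chord distance
#'   on the unit sphere) of the source-to-electrode mixing.
#' @param signal_sd target channel signal scale (microvolts).
#' @param gain_spread log-SD of the per-channel gain.
#' @param drift_slope_range linear drift slope range (uV / sample).
#' @param line_hz,line_amplitude mains frequency and mean amplitude.
#' @param noise_floor white noise floor SD (microvolts).
#' @param floor_spread log-SD of the per-channel noise floor
#'   (electrode contact impedance varies across the cap).
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 32L, duration_seconds = 300,
                           fs = 200, montage = montage_std32(),
                           source_count = 100L, source_width = 1.2,
                           signal_sd = 20, gain_spread = 0.05,
                           drift_slope_range = c(-1, 8),
                           line_hz = 60, line_amplitude = 5,
                           noise_floor = 2, floor_spread = 0.03,
                           seed = 1L) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (n_channels != length(montage$labels))
    stop("n_channels must match the montage")
  stopifnot(duration_seconds > 0, fs > 0, source_count >= 2L,
            signal_sd > 0, noise_floor >= 0, line_amplitude >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a clean synthetic EEG session
#'
#' Deterministic given `spec$seed`.  See [synthetic_spec()] for the
#' generative model.  "Clean" means free of injected bad channels;
#' the output still contains drift and line noise so the full
#' pipeline (temporary high-pass, line-noise removal, detection) is
#' exercised.
#'
#' @param spec a [synthetic_spec()].
#' @return an [recording()].
#' @export
generate_clean <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_seconds * spec$fs)
    nc <- spec$n_channels
    mont <- normalize_montage(spec$montage)
    pos <- mont$positions
    # dipolar sources on the upper half of the sphere: each source
    # projects a signed two-pole topography (volume-conducted scalp
    # fields are dipolar, so the channel-mean common mode stays weak
    # and mean subtraction leaves healthy residuals on every channel)
    sz <- stats::runif(spec$source_count, 0.05, 1)
    saz <- stats::runif(spec$source_count, 0, 2 * pi)
    sr <- sqrt(1 - sz^2)
    spos <- cbind(sr * cos(saz), sr * sin(saz), sz)
    kern <- function(centers) {
      d2 <- outer(rowSums(pos^2), rowSums(centers^2), `+`) -
        2 * tcrossprod(pos, centers)
      exp(-pmax(d2, 0) / (2 * spec$source_width^2))
    }
    # random dipole orientations (radial/tangential mixture, as for
    # gyral/sulcal cortex) so no electrode sits at a node of every
    # source topography
    tang <- matrix(stats::rnorm(3 * spec$source_count), ncol = 3L)
    tang <- tang / sqrt(rowSums(tang^2))
    polep <- spos + 0.3 * tang
    polen <- spos - 0.3 * tang
    polep <- polep / sqrt(rowSums(polep^2))
    polen <- polen / sqrt(rowSums(polen^2))
    # distance-decay dipolar mixing; rows are normalized (scaling a
    # weight vector leaves all correlations unchanged) and channel
    # gain heterogeneity is reintroduced explicitly via `gain`
    W <- kern(polep) - kern(polen)
    # center topographies across the montage: scalp potential is only
    # defined up to a reference, so the clean truth lives in
    # average-reference space; this keeps the per-channel residual
    # after mean subtraction as large as the raw signal (no channel
    # is structurally cancelled by referencing)
    W <- sweep(W, 2L, colMeans(W))
    W <- W / sqrt(rowSums(W^2))
    S <- t(vapply(seq_len(spec$source_count),
                  function(i) pink_series(n, spec$fs), numeric(n)))
    gain <- exp(stats::rnorm(nc, 0, spec$gain_spread))
    sig <- (W %*% S) * spec$signal_sd * gain
    # linear drift, uV per sample
    slope <- stats::runif(nc, spec$drift_slope_range[1L],
                          spec$drift_slope_range[2L])
    t_idx <- seq_len(n) - 1
    drift <- outer(slope, t_idx)
    # 60 Hz line with slow shared amplitude / phase wander
    tt <- t_idx / spec$fs
    am <- 1 + 0.3 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi))
    ph <- 0.8 * sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi))
    lg <- exp(stats::rnorm(nc, 0, 0.1))
    line <- outer(lg * spec$line_amplitude, rep(1, n)) *
      rep(am, each = nc) * cos(2 * pi * spec$line_hz *
                                 rep(tt, each = nc) + rep(ph, each = nc))
    dim(line) <- c(nc, n)
    floor_sd <- spec$noise_floor * exp(stats::rnorm(nc, 0, spec$floor_spread))
    floor_n <- matrix(stats::rnorm(nc * n), nc, n) * floor_sd
    recording(sig + drift + line + floor_n, spec$fs, mont)
  })
}

#' Ground truth for injected bad channels
#'
#' @param injected named character vector: names are channel labels,
#'   values are noise types among `gaussian`, `low_amplitude`,
#'   `shuffled`, `correlated_pair`.
#' @param session_id identifier.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(injected, session_id = "session") {
  types <- c("gaussian", "low_amplitude", "shuffled", "correlated_pair")
  if (!all(injected %in% types))
    stop("unknown injection type(s): ",
         paste(setdiff(injected, types), collapse = ", "))
  if (anyDuplicated(names(injected)))
    stop("injected channels must be distinct")
  if (sum(injected == "correlated_pair") %% 2L != 0L)
    stop("correlated_pair channels must come in pairs")
  structure(list(injected = injected, session_id = session_id),
            class = "ground_truth")
}

#' Inject synthetic bad channels
#'
#' The four injection methods:
#' * `gaussian` - add Gaussian noise with amplitude 8 times the
#'   channel standard deviation;
#' * `low_amplitude` - attenuate the channel to one tenth, simulating
#'   a weak electrical connection (the recorded channel keeps a fresh
#'   amplifier noise floor of `noise_floor` microvolts, which does
#'   not attenuate with the scalp signal);
#' * `shuffled` - temporally shuffle the samples, making the channel
#'   maximally uncorrelated with the others at identical amplitude
#'   distribution;
#' * `correlated_pair` - replace each pair of channels with
#'   amplitude-normalized copies of `donor` (the highest-amplitude
#'   channel of a different session), making them fully correlated.
#'
#' @param rec an [recording()] (cleaned base session).
#' @param plan a [ground_truth()] whose channels exist in `rec`.
#' @param donor numeric vector (same length as the data) used for
#'   `correlated_pair`; required when the plan contains pairs.
#' @param noise_floor amplifier noise SD for `low_amplitude`.
#' @param gaussian_amplitude noise multiple for `gaussian`.
#' @param seed integer seed for the injection randomness.
#' @return the modified recording.
#' @export
inject_bad_channels <- function(rec, plan, donor = NULL, noise_floor = 2,
                                gaussian_amplitude = 8, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(plan, "ground_truth"))
  chans <- names(plan$injected)
  if (!all(chans %in% rec$montage$labels))
    stop("plan references unknown channels")
  n <- ncol(rec$data)
  if (any(plan$injected == "correlated_pair")) {
    if (is.null(donor)) stop("correlated_pair injection requires a donor")
    donor <- rep_len(donor, n)  # repeated or trimmed to session length
  }
  with_seed(seed, {
    out <- rec
    for (ch in chans) {
      x <- rec$data[ch, ]
      out$data[ch, ] <- switch(
        plan$injected[[ch]],
        gaussian = x + stats::rnorm(n, 0, gaussian_amplitude * stats::sd(x)),
        low_amplitude = 0.1 * x + stats::rnorm(n, 0, noise_floor),
        shuffled = x[sample.int(n)],
        correlated_pair = donor / robust_sd(donor) * robust_sd(x))
    }
    out
  })
}
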