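#' Line-noise removal parameters
#'
#' Defaults follow the standard multitaper harmonic-regression setup
#' for 60 Hz mains: candidate frequencies at 60 Hz and its harmonics
#' below Nyquist, 4-s windows sliding by 1 s, taper bandwidth 2 Hz
#' (7 Slepian tapers), significance threshold p < 0.01, a +/- 2 Hz
#' frequency scan around each candidate, sigmoidal stitching constant
#' tau = 100 samples, and at most 10 removal iterations.
#'
#' @param line_frequencies_hz candidate line frequencies; `NULL` means
#'   60 Hz and all multiples below Nyquist, resolved at run time.
#' @param window_seconds sliding-window length W (s).
#' @param slide_seconds window slide (s).
#' @param taper_bandwidth_hz taper bandwidth TBW (Hz).
#' @param p_threshold significance level for the Thomson F-test.
#' @param f_scan_bandwidth_hz half-width of the frequency scan (Hz).
#' @param tau sigmoid stitching constant, in samples.
#' @param max_iterations maximum removal passes per channel.
#' @param detection_highpass_hz temporary high-pass cutoff used before
#'   estimating line noise (Hz).
#' @param scan_correction apply a Sidak correction for the number of
#'   independent frequencies examined by the scan when judging
#'   significance (see the methods vignette).
#' @return a `line_noise_params` list.
#' @export
line_noise_params <- function(line_frequencies_hz = NULL,
                              window_seconds = 4,
                              slide_seconds = 1,
                              taper_bandwidth_hz = 2,
                              p_threshold = 0.01,
                              f_scan_bandwidth_hz = 2,
                              tau = 100,
                              max_iterations = 10,
                              detection_highpass_hz = 1,
                              scan_correction = TRUE) {
  p <- list(line_frequencies_hz = line_frequencies_hz,
            window_seconds = window_seconds, slide_seconds = slide_seconds,
            taper_bandwidth_hz = taper_bandwidth_hz,
            p_threshold = p_threshold,
            f_scan_bandwidth_hz = f_scan_bandwidth_hz, tau = tau,
            max_iterations = max_iterations,
            detection_highpass_hz = detection_highpass_hz,
            scan_correction = isTRUE(scan_correction))
  stopifnot(p$window_seconds > 0, p$slide_seconds > 0,
            p$taper_bandwidth_hz * p$window_seconds > 1,
            p$p_threshold > 0, p$p_threshold < 1,
            p$f_scan_bandwidth_hz >= 0, p$tau > 0, p$max_iterations >= 1)
  structure(p, class = "line_noise_params")
}

#' Noisy-channel detection parameters
#'
#' Thresholds for the detection battery.  Robust z-score cutoffs are 5
#' for both the deviation and high-frequency noisiness criteria; a
#' channel is bad-by-correlation when its 98th-percentile absolute
#' window correlation falls below 0.4 in strictly more than 1% of 1-s
#' windows; RANSAC flags channels whose spline prediction correlates
#' below 0.75 in more than 40% of 5-s windows.
#'
#' @param robust_deviation_threshold |robust z| cutoff for deviation.
#' @param correlation_window_seconds correlation window length (s).
#' @param correlation_threshold low-correlation cutoff.
#' @param bad_time_fraction window fraction above which low
#'   correlation flags the channel (strict inequality).
#' @param correlation_percentile percentile of |r| used as the
#'   "maximum" absolute correlation.
#' @param hf_noise_threshold robust z cutoff for noisiness.
#' @param hf_split_hz low/high frequency split (Hz).
#' @param ransac_subset_fraction fraction of good channels per
#'   predictor subset.
#' @param ransac_correlation_threshold prediction correlation cutoff.
#' @param ransac_bad_fraction window fraction above which poor
#'   prediction flags the channel.
#' @param ransac_window_seconds RANSAC window length (s).
#' @param ransac_sample_count number of random predictor subsets.
#' @param ransac_enabled set `FALSE` to disable the predictability
#'   criterion.
#' @param dropout_fraction fraction of constant/tiny windows above
#'   which the channel is bad-by-dropout.
#' @return a `noisy_params` list.
#' @export
noisy_params <- function(robust_deviation_threshold = 5,
                         correlation_window_seconds = 1,
                         correlation_threshold = 0.4,
                         bad_time_fraction = 0.01,
                         correlation_percentile = 98,
                         hf_noise_threshold = 5,
                         hf_split_hz = 50,
                         ransac_subset_fraction = 0.25,
                         ransac_correlation_threshold = 0.75,
                         ransac_bad_fraction = 0.4,
                         ransac_window_seconds = 5,
                         ransac_sample_count = 50,
                         ransac_enabled = TRUE,
                         dropout_fraction = 0.01) {
  p <- as.list(environment())
  num <- p[setdiff(names(p), "ransac_enabled")]
  stopifnot(all(vapply(num, function(v) is.numeric(v) && v > 0, TRUE)),
            p$bad_time_fraction <= 1, p$ransac_subset_fraction <= 1,
            p$ransac_bad_fraction <= 1, p$dropout_fraction <= 1,
            p$correlation_percentile > 0, p$correlation_percentile <= 100)
  structure(p, class = "noisy_params")
}

#' Robust referencing parameters
#'
#' @param initial_estimate "median" (default) or "mean": the initial
#'   robust estimate of the true mean in phase 1.
#' @param max_iterations phase-1 iteration cap (default 4; for most
#'   recordings the loop converges after one pass).
#' @param reference_channels labels over which the reference mean is
#'   taken; `NULL` means the recording's evaluation channels.
#' @param bad_fraction_abort abort if more than this fraction of the
#'   reference channels accumulates as bad (the reference would be
#'   meaningless).
#' @return a `reference_params` list.
#' @export
reference_params <- function(initial_estimate = c("median", "mean"),
                             max_iterations = 4,
                             reference_channels = NULL,
                             bad_fraction_abort = 0.75) {
  initial_estimate <- match.arg(initial_estimate)
  stopifnot(max_iterations >= 1, bad_fraction_abort > 0,
            bad_fraction_abort <= 1)
  structure(list(initial_estimate = initial_estimate,
                 max_iterations = max_iterations,
                 reference_channels = reference_channels,
                 bad_fraction_abort = bad_fraction_abort),
            class = "reference_params")
}

#' Reporting parameters
#' @param window_seconds statistics window length (s).
#' @return a `report_params` list.
#' @export
report_params <- function(window_seconds = 1) {
  stopifnot(window_seconds > 0)
  structure(list(window_seconds = window_seconds), class = "report_params")
}

#' Full pipeline configuration
#'
#' Bundles the stage parameter sets and the random seed.  The
#' defaults reproduce the documented defaults of every stage.
#'
#' @param line_noise,noisy,reference,report stage parameter lists.
#' @param seed integer seed controlling all randomized steps (RANSAC
#'   subset draws).
#' @return a `prep_config` list.
#' @export
prep_config <- function(line_noise = line_noise_params(),
                        noisy = noisy_params(),
                        reference = reference_params(),
                        report = report_params(),
                        seed = 4242L) {
  stopifnot(inherits(line_noise, "line_noise_params"),
            inherits(noisy, "noisy_params"),
            inherits(reference, "reference_params"),
            inherits(report, "report_params"))
  structure(list(line_noise = line_noise, noisy = noisy,
                 reference = reference, report = report,
                 seed = as.integer(seed)),
            class = "prep_config")
}

#' Read a flat key=value configuration file
#'
#' Keys use `section.name` form (`noisy.ransac_sample_count = 25`).
#' Lines starting with `#` or `;` are comments.  Unknown keys are an
#' error.  Values are parsed as logical, numeric, or comma lists of
#' numerics, in that order of preference.
#'
#' @param path config file path.
#' @param base configuration the file overrides (default
#'   [prep_config()]).
#' @return a `prep_config`.
#' @export
read_config <- function(path, base = prep_config()) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  cfg <- unclass(base)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    parsed <- if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
    else if (!anyNA(suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))))
      as.numeric(strsplit(val, ",")[[1L]])
    else val
    if (key == "seed") { cfg$seed <- as.integer(parsed); next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% names(cfg)[1:4])
      stop("unknown config key: ", key)
    if (!parts[2L] %in% names(cfg[[parts[1L]]]))
      stop("unknown config key: ", key)
    cfg[[parts[1L]]][[parts[2L]]] <- parsed
  }
  prep_config(cfg$line_noise, cfg$noisy, cfg$reference, cfg$report, cfg$seed)
}
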