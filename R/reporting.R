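#' Robust window deviations
#'
#' `D[c, w]` is 0.7413 times the interquartile range of channel `c`
#' in window `w` (the robust window deviation).
#'
#' @param rec an [recording()].
#' @param grid a [partition_windows()] grid (default: 1-s windows).
#' @return channels x windows matrix.
#' @export
compute_window_deviations <- function(rec,
                                      grid = partition_windows(
                                        ncol(rec$data), rec$fs, 1)) {
  x <- rec$data[rec$evaluation_channels, , drop = FALSE]
  D <- window_apply(x, grid, function(w) apply(w, 1L, robust_sd))
  rownames(D) <- rec$evaluation_channels
  D
}

#' Dataset summary measures
#'
#' Summary statistics of one processing stage, computed from the
#' retained windowed arrays: the overall mean (and the mean of
#' per-channel medians) of the 98th-percentile absolute window
#' correlations, the overall median of the robust window deviations
#' D, the robust deviation ratio robust_sd(D)/median(D), the fraction
#' of reference channels interpolated, and the Pearson correlation
#' between the ordinary average reference and the robust reference.
#'
#' @param rec the referenced [recording()] (used for the deviation
#'   array of the final stage and the reference comparison).
#' @param result a `reference_result` from [perform_reference()].
#' @param original the line-noise-cleaned, unreferenced recording;
#'   needed for `reference_correlation` (ordinary average reference).
#'   If omitted, that field is `NA`.
#' @param stage which statistics snapshot to summarize: `"final"`,
#'   `"original"` or `"before_interp"`.
#' @return a `dataset_summary` list.
#' @export
dataset_summary <- function(rec, result, original = NULL,
                            stage = c("final", "original", "before_interp")) {
  stage <- match.arg(stage)
  stopifnot(inherits(result, "reference_result"))
  snap <- switch(stage, final = result$noisy_final,
                 original = result$noisy_original,
                 before_interp = result$noisy_before_interp)
  if (is.null(snap)) stop("missing statistics snapshot for stage ", stage)
  mc <- snap$stats$max_correlation
  chan_med <- apply(mc, 1L, stats::median, na.rm = TRUE)
  D <- compute_window_deviations(rec)
  dvec <- as.vector(D)
  ref_chans <- rec$evaluation_channels
  refcor <- NA_real_
  if (!is.null(original)) {
    avg_ref <- colMeans(original$data[ref_chans, , drop = FALSE])
    refcor <- stats::cor(avg_ref, result$reference_signal)
  }
  structure(list(
    mean_max_correlation = mean(mc, na.rm = TRUE),
    mean_median_max_correlation = mean(chan_med, na.rm = TRUE),
    median_max_correlation = stats::median(chan_med, na.rm = TRUE),
    median_window_deviation = stats::median(dvec),
    deviation_ratio = robust_sd(dvec) / stats::median(dvec),
    interpolated_fraction = length(result$interpolated) / length(ref_chans),
    reference_correlation = refcor,
    stage = stage), class = "dataset_summary")
}

# distance of m to the interval [lo, hi] (0 inside)
interval_distance <- function(m, lo, hi) {
  if (is.na(m)) return(NA_real_)
  if (m < lo) lo - m else if (m > hi) m - hi else 0
}

#' Issue flags for a processed dataset
#'
#' Three heuristics flagging datasets that may have problems after
#' robust referencing:
#' * `corr_not_improved` - referencing did not move the mean of the
#'   per-channel median max window correlation closer to the interval
#'   `[0.80, 0.91]` when it started outside it (distance-to-interval
#'   rule);
#' * `corr_too_high` - after referencing the mean max correlation
#'   exceeds 0.91 and the median exceeds 0.95 (suggesting residual
#'   common additive noise);
#' * `too_many_interpolated` - more than 25% of the reference
#'   channels were interpolated.
#'
#' @param before,after `dataset_summary` objects for the original and
#'   final stages.
#' @param corr_interval target interval for the median-max
#'   correlation.
#' @param interp_limit interpolated-fraction limit.
#' @return an `issue_flags` list of three logicals.
#' @export
flag_issues <- function(before, after, corr_interval = c(0.80, 0.91),
                        interp_limit = 0.25) {
  d_before <- interval_distance(before$mean_median_max_correlation,
                                corr_interval[1L], corr_interval[2L])
  d_after <- interval_distance(after$mean_median_max_correlation,
                               corr_interval[1L], corr_interval[2L])
  structure(list(
    corr_not_improved = isTRUE(d_before > 0 && d_after >= d_before),
    corr_too_high = isTRUE(after$mean_max_correlation > 0.91 &&
                             after$median_max_correlation > 0.95),
    too_many_interpolated = isTRUE(after$interpolated_fraction >
                                     interp_limit)), class = "issue_flags")
}

#' Collection summary table
#'
#' Aggregates a list of dataset summaries into one row per dataset
#' plus a median row, and lists the flagged issues per dataset when
#' issue flags are supplied.
#'
#' @param summaries non-empty list of `dataset_summary` objects.
#' @param flags optional list of `issue_flags`, same length.
#' @param ids optional dataset identifiers.
#' @return a data.frame; the final row (`id = "median"`) holds
#'   per-column medians.  Attribute `issues` lists flagged datasets.
#' @export
collection_summary <- function(summaries, flags = NULL, ids = NULL) {
  if (length(summaries) == 0L) stop("empty collection")
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  num_fields <- c("mean_max_correlation", "mean_median_max_correlation",
                  "median_max_correlation", "median_window_deviation",
                  "deviation_ratio", "interpolated_fraction",
                  "reference_correlation")
  tab <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(s[num_fields])))
  tab <- cbind(id = ids, tab)
  med <- vapply(tab[num_fields], stats::median, numeric(1), na.rm = TRUE)
  tab <- rbind(tab, cbind(id = "median", as.data.frame(as.list(med))))
  rownames(tab) <- NULL
  issues <- list()
  if (!is.null(flags)) {
    stopifnot(length(flags) == length(summaries))
    for (i in seq_along(flags)) {
      on <- names(flags[[i]])[vapply(flags[[i]], isTRUE, TRUE)]
      if (length(on)) issues[[ids[i]]] <- on
    }
  }
  attr(tab, "issues") <- issues
  tab
}

#' Write the machine-readable dataset report
#'
#' JSON report with the dataset summaries at the three statistics
#' stages, the issue flags, the per-category bad channels and the
#' interpolated set.
#'
#' @param rec the referenced recording.
#' @param result a `reference_result`.
#' @param original the line-noise-cleaned input (for the reference
#'   correlation).
#' @param path output path (`.json`).
#' @return the report list, invisibly.
#' @export
write_report <- function(rec, result, original = NULL, path) {
  stages <- c("original", "before_interp", "final")
  sums <- lapply(stages, function(s)
    unclass(dataset_summary(rec, result, original, stage = s)))
  names(sums) <- stages
  flags <- flag_issues(structure(sums$original, class = "dataset_summary"),
                       structure(sums$final, class = "dataset_summary"))
  report <- list(
    summary = sums,
    issues = unclass(flags),
    bad_by = lapply(result$noisy_final$bad_by, as.character),
    bad_by_original = lapply(result$noisy_original$bad_by, as.character),
    interpolated = as.character(result$interpolated),
    still_bad = as.character(result$still_bad),
    iterations_used = result$iterations_used)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
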