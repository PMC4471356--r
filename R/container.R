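# Hierarchical result container, one JSON file.
#
# Layout (one group per pipeline stage, arrays as named datasets):
#   header/       format version, package version, channel labels, fs
#   config/       the prep_config used (scalars / small vectors)
#   montage/      labels + positions
#   data/         processed signal (channels x samples)
#   reference/    reference_signal, interpolated, still_bad, iterations
#   noisy/<stage> bad_by sets + windowed statistic arrays for the
#                 original / before_interp / final snapshots
#
# Numeric arrays are serialized as "%.17g" strings with their dims, so
# the read-back double is bit-identical; integers and strings
# round-trip exactly through JSON.

enc_array <- function(x) {
  list(.array = "f64", dim = if (is.null(dim(x))) length(x) else dim(x),
       dimnames = if (is.null(dim(x))) list() else dimnames(x),
       values = sprintf("%.17g", as.vector(x)))
}

dec_array <- function(a) {
  vals <- unlist(a$values)
  v <- rep(NA_real_, length(vals))
  ok <- vals != "NA"
  v[ok] <- as.numeric(vals[ok])
  d <- unlist(a$dim)
  if (length(d) > 1L) {
    v <- array(v, dim = d)
    dn <- a$dimnames
    if (!is.null(dn) && length(dn) == length(d))
      dimnames(v) <- lapply(dn, function(n) if (length(n)) unlist(n) else NULL)
  }
  v
}

enc_noisy <- function(nz) {
  list(bad_by = lapply(nz$bad_by, as.character),
       unusable = as.character(nz$unusable),
       channels = as.character(nz$channels),
       stats = list(
         deviation_z = enc_array(nz$stats$deviation_z),
         max_correlation = enc_array(nz$stats$max_correlation),
         noise_z = enc_array(nz$stats$noise_z),
         ransac_correlation = enc_array(nz$stats$ransac_correlation),
         deviation_channel_z = enc_array(nz$stats$deviation_channel_z),
         noisiness = enc_array(nz$stats$noisiness)))
}

dec_noisy <- function(g, params) {
  st <- lapply(g$stats, dec_array)
  # restore channel rownames on the windowed arrays
  ch <- unlist(g$channels)
  for (k in c("deviation_z", "max_correlation", "noise_z",
              "ransac_correlation"))
    if (!is.null(dim(st[[k]]))) rownames(st[[k]]) <- ch
  bad_by <- lapply(g$bad_by, function(v) as.character(unlist(v)))
  structure(list(bad_by = bad_by,
                 unusable = as.character(unlist(g$unusable)),
                 bad_all = Reduce(union, c(bad_by, list(character(0)))),
                 channels = ch, stats = st, params = params),
            class = "noisy_channels")
}

#' Write the pipeline result container
#'
#' Serializes the processed recording, the robust-reference result
#' (reference signal, interpolated channels, three statistics
#' snapshots) and the configuration into one hierarchical JSON
#' container.  Integers and strings round-trip bit-exactly; numeric
#' arrays round-trip to full double precision ("%.17g").
#'
#' @param rec the processed [recording()].
#' @param result a `reference_result` from [perform_reference()].
#' @param path output path.
#' @param config the [prep_config()] used (stored for re-run
#'   reproducibility).
#' @return `path`, invisibly.
#' @export
write_result <- function(rec, result, path, config = prep_config()) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(result, "reference_result"))
  flat_cfg <- lapply(unclass(config)[1:4], function(sec)
    lapply(unclass(sec), function(v) if (is.null(v)) NULL else v))
  obj <- list(
    header = list(format = "eegpipe-container", version = 1L,
                  package_version =
                    as.character(utils::packageVersion("eegpipe")),
                  fs = rec$fs, n_samples = ncol(rec$data),
                  labels = rec$montage$labels,
                  evaluation_channels = rec$evaluation_channels),
    config = c(flat_cfg, list(seed = config$seed)),
    montage = list(labels = rec$montage$labels,
                   positions = enc_array(rec$montage$positions)),
    data = enc_array(rec$data),
    reference = list(reference_signal = enc_array(result$reference_signal),
                     interpolated = as.character(result$interpolated),
                     still_bad = as.character(result$still_bad),
                     phase1_bad = as.character(result$phase1_bad),
                     iterations_used = result$iterations_used),
    noisy = list(original = enc_noisy(result$noisy_original),
                 before_interp = enc_noisy(result$noisy_before_interp),
                 final = enc_noisy(result$noisy_final)))
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) stop("cannot write container: ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a pipeline result container
#'
#' @param path container path written by [write_result()].
#' @return list with `recording`, `result` (a `reference_result`)
#'   and `config`.
#' @export
read_result <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$header$format) ||
      obj$header$format != "eegpipe-container")
    stop("not an eegpipe result container: ", path)
  for (grp in c("montage", "data", "reference", "noisy"))
    if (is.null(obj[[grp]])) stop("container missing group: ", grp)
  for (stg in c("original", "before_interp", "final"))
    if (is.null(obj$noisy[[stg]]))
      stop("container missing statistics snapshot: ", stg)
  labels <- unlist(obj$header$labels)
  mont <- montage(labels, dec_array(obj$montage$positions))
  data <- dec_array(obj$data)
  rec <- recording(data, obj$header$fs, mont,
                   unlist(obj$header$evaluation_channels))
  cfg <- obj$config
  npar <- do.call(noisy_params, cfg$noisy[!vapply(cfg$noisy, is.null, TRUE)])
  result <- structure(list(
    reference_signal = dec_array(obj$reference$reference_signal),
    interpolated = as.character(unlist(obj$reference$interpolated)),
    still_bad = as.character(unlist(obj$reference$still_bad)),
    phase1_bad = as.character(unlist(obj$reference$phase1_bad)),
    iterations_used = obj$reference$iterations_used,
    noisy_original = dec_noisy(obj$noisy$original, npar),
    noisy_before_interp = dec_noisy(obj$noisy$before_interp, npar),
    noisy_final = dec_noisy(obj$noisy$final, npar)),
    class = "reference_result")
  list(recording = rec, result = result, config = cfg)
}
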