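#' Read an EDF or BDF file
#'
#' Minimal reader for continuous EDF (16-bit) and BDF (BioSemi,
#' 24-bit) files: parses the ASCII header, decodes the data records
#' and applies the per-signal physical scaling.  Annotation channels
#' (`EDF Annotations` / `BDF Annotations` / `Status`) are dropped.
#' Physical units are converted to microvolts when the dimension
#' field is V, mV or uV; other units are passed through unchanged.
#'
#' @param path file path; BDF is recognized by its 0xFF + "BIOSEMI"
#'   magic, anything else is treated as EDF.
#' @return list with `data` (channels x samples, double, microvolts),
#'   `fs` (Hz) and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  is_bdf <- magic[1L] == as.raw(255L) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  afield <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  invisible(afield(80L)); invisible(afield(80L))   # patient, recording ids
  invisible(afield(8L)); invisible(afield(8L))     # date, time
  header_bytes <- as.integer(afield(8L))
  invisible(afield(44L))                           # reserved
  n_records <- as.integer(afield(8L))
  record_sec <- as.numeric(afield(8L))
  ns <- as.integer(afield(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF/BDF header: ", path)
  per <- function(n) vapply(seq_len(ns), function(i) afield(n), "")
  labels <- per(16L)
  invisible(per(80L))                              # transducer
  dims <- per(8L)
  pmin <- as.numeric(per(8L)); pmax <- as.numeric(per(8L))
  dmin <- as.numeric(per(8L)); dmax <- as.numeric(per(8L))
  invisible(per(80L))                              # prefiltering
  nsamp <- as.integer(per(8L))
  invisible(readBin(con, "raw", 32L * ns))         # reserved
  if (!is.na(header_bytes)) {
    used <- 256L + 256L * ns
    if (header_bytes > used) invisible(readBin(con, "raw", header_bytes - used))
  }
  drop <- grepl("Annotations|^Status$", labels)
  bps <- if (is_bdf) 3L else 2L
  rec_len <- sum(nsamp) * bps
  payload <- readBin(con, "raw", n_records * rec_len)
  if (length(payload) < n_records * rec_len) {
    n_records <- length(payload) %/% rec_len
    payload <- payload[seq_len(n_records * rec_len)]
  }
  if (n_records < 1L) stop("no data records in ", path)
  decode <- function(raw_vec) {
    if (is_bdf) {
      m <- matrix(as.integer(raw_vec), nrow = 3L)
      v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
      ifelse(v >= 8388608, v - 16777216, v)
    } else {
      readBin(raw_vec, "integer", length(raw_vec) %/% 2L, size = 2L,
              signed = TRUE, endian = "little")
    }
  }
  offs <- c(0L, cumsum(nsamp * bps))
  sig <- vector("list", ns)
  pm <- matrix(payload, ncol = n_records)   # one column per record
  for (i in seq_len(ns)) {
    if (drop[i]) next
    chunk <- pm[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]
    dig <- decode(as.raw(chunk))
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys <- pmin[i] + (dig - dmin[i]) * scale
    u <- toupper(dims[i])
    if (u == "V") phys <- phys * 1e6
    else if (u == "MV") phys <- phys * 1e3
    sig[[i]] <- phys
  }
  keep <- which(!drop)
  if (length(unique(nsamp[keep])) != 1L)
    stop("mixed per-signal sampling rates are not supported: ", path)
  fs <- nsamp[keep[1L]] / record_sec
  if (!is.finite(fs) || fs <= 0) stop("non-finite sampling rate in ", path)
  data <- do.call(rbind, sig[keep])
  storage.mode(data) <- "double"
  list(data = data, fs = fs, labels = labels[keep])
}

# raw float64 matrix + JSON sidecar header {fs, labels, units, data_file}
read_raw_matrix <- function(header_path) {
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  for (k in c("fs", "labels", "data_file"))
    if (is.null(hdr[[k]])) stop("raw-matrix header missing field: ", k)
  data_path <- file.path(dirname(header_path), hdr$data_file)
  nch <- length(hdr$labels)
  bytes <- file.size(data_path)
  n <- bytes %/% 8L
  if (n %% nch != 0L)
    stop("data file length is not a multiple of the channel count")
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n, size = 8L, endian = "little")
  # channel-major layout: all samples of channel 1, then channel 2, ...
  data <- t(matrix(v, nrow = n %/% nch, ncol = nch))
  units <- if (is.null(hdr$units)) "uV" else hdr$units
  mult <- switch(toupper(units), "V" = 1e6, "MV" = 1e3, 1)
  list(data = data * mult, fs = as.numeric(hdr$fs),
       labels = as.character(hdr$labels))
}

#' Read a recording from disk
#'
#' Dispatches on extension: `.edf`/`.bdf` are parsed by [read_edf()];
#' `.json` is taken as a raw-matrix sidecar header with fields
#' `fs`, `labels`, `units` and `data_file` (flat little-endian
#' float64, channel-major).  Electrode positions come from
#' `montage_path` (.sfp-style text) and must cover every data channel;
#' montage order defines the channel order of the result.
#'
#' @param path signal file (EDF/BDF or JSON header).
#' @param montage_path montage file; required, since neither format
#'   embeds positions.
#' @param evaluation_channels optional subset treated as EEG.
#' @return an [recording()].
#' @export
read_recording <- function(path, montage_path, evaluation_channels = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                edf = read_edf(path),
                bdf = read_edf(path),
                json = read_raw_matrix(path),
                stop("unknown recording format: .", ext))
  if (missing(montage_path) || is.null(montage_path))
    stop("montage_path is required: signal files do not embed positions")
  mont <- read_montage(montage_path)
  if (length(mont$labels) != nrow(raw$data))
    stop(sprintf("channel-count mismatch: %d montage labels vs %d signals",
                 length(mont$labels), nrow(raw$data)))
  if (!setequal(mont$labels, raw$labels))
    stop("montage labels do not match signal labels")
  data <- raw$data[match(mont$labels, raw$labels), , drop = FALSE]
  recording(data, raw$fs, mont, evaluation_channels)
}
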