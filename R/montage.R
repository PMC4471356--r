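#' Electrode montage
#'
#' A montage is an ordered set of channel labels with 3-D Cartesian
#' electrode positions.  Positions may be in arbitrary length units;
#' all spatial computations (spherical-spline interpolation, RANSAC
#' prediction) first project them onto the unit sphere centered at the
#' position centroid.
#'
#' @param labels character vector of unique, non-empty channel names.
#' @param positions numeric matrix with one row per label and columns
#'   x, y, z.  Every position must be finite with nonzero norm.
#' @return An object of class `eeg_montage`: a list with elements
#'   `labels` and `positions` (rownames set to the labels).
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  if (length(labels) == 0L || anyNA(labels) || any(!nzchar(labels)))
    stop("montage labels must be non-empty strings")
  if (anyDuplicated(labels))
    stop("montage labels must be unique")
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix matching the labels")
  if (!all(is.finite(positions)))
    stop("montage positions must be finite")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0))
    stop("montage positions must have nonzero norm")
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = positions),
            class = "eeg_montage")
}

#' Project montage positions to the unit sphere
#'
#' Re-centers positions at their centroid and scales each to unit
#' norm.  Idempotent: normalizing an already-normalized montage leaves
#' it unchanged (up to floating-point round-off).
#'
#' @param m an `eeg_montage`.
#' @param center logical; re-center at the centroid before scaling.
#'   Default `FALSE`: electrode coordinates are head-centered by
#'   convention, and the centroid of a hemispheric cap lies far above
#'   the head center, which would warp angular distances.
#' @return a normalized `eeg_montage`.
#' @export
normalize_montage <- function(m, center = FALSE) {
  stopifnot(inherits(m, "eeg_montage"))
  p <- m$positions
  if (center) {
    ctr <- colMeans(p)
    # a centroid of an (approximately) sphere-covering cap layout sits
    # inside the sphere; for already unit-norm symmetric layouts the
    # shift is small and re-normalization is idempotent
    p <- sweep(p, 2L, ctr)
    if (any(sqrt(rowSums(p^2)) < 1e-12))
      p <- m$positions  # degenerate centering; fall back to raw positions
  }
  p <- p / sqrt(rowSums(p^2))
  montage(m$labels, p)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s\n", length(x$labels),
              paste(utils::head(x$labels, 8L), collapse = ", ")))
  invisible(x)
}

#' Read a montage from an .sfp-style text file
#'
#' Whitespace-delimited rows of `label x y z`.  Lines starting with
#' `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return an `eeg_montage`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty montage file: ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 4L))
    stop("montage rows must be 'label x y z': ", path)
  labels <- vapply(parts, `[[`, "", 1L)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(pos)) stop("non-numeric coordinates in montage file: ", path)
  montage(labels, pos)
}

#' Write a montage to an .sfp-style text file
#' @param m an `eeg_montage`.
#' @param path file path.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  writeLines(sprintf("%s\t%.10f\t%.10f\t%.10f", m$labels,
                     m$positions[, 1L], m$positions[, 2L], m$positions[, 3L]),
             path)
  invisible(path)
}

# spherical linear interpolation between two unit vectors
slerp <- function(a, b, t) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - t) * omega) * a + sin(t * omega) * b) / sin(omega)
}

#' Standard 32-channel cap layout on the unit sphere
#'
#' An idealized 10-10 style 32-electrode layout.  Anchor electrodes
#' (midline, outer ring, C3/C4) are placed from the standard arc
#' fractions of the nasion-inion and ear-to-ear great circles;
#' intermediate electrodes are spherical midpoints of their row
#' neighbors.  Coordinates: +x right ear, +y nasion, +z vertex.
#'
#' @return an `eeg_montage` with 32 unit-sphere positions.
#' @export
montage_std32 <- function() {
  # (inclination alpha from vertex, azimuth beta from nasion, +right)
  ang <- function(alpha, beta) {
    a <- alpha * pi / 180; b <- beta * pi / 180
    c(sin(a) * sin(b), sin(a) * cos(b), cos(a))
  }
  p <- list(
    Fpz = ang(72, 0), Fp1 = ang(72, -18), Fp2 = ang(72, 18),
    F7  = ang(72, -54), F8  = ang(72, 54),
    T7  = ang(72, -90), T8  = ang(72, 90),
    P7  = ang(72, -126), P8 = ang(72, 126),
    O1  = ang(72, -162), O2 = ang(72, 162), Oz = ang(72, 180),
    Fz  = ang(36, 0), Cz = c(0, 0, 1), Pz = ang(36, 180),
    POz = ang(54, 180),
    C3  = ang(36, -90), C4 = ang(36, 90)
  )
  p$F3  <- slerp(p$Fz, p$F7, 0.5);  p$F4  <- slerp(p$Fz, p$F8, 0.5)
  p$P3  <- slerp(p$Pz, p$P7, 0.5);  p$P4  <- slerp(p$Pz, p$P8, 0.5)
  p$FCz <- slerp(p$Fz, p$Cz, 0.5);  p$CPz <- slerp(p$Pz, p$Cz, 0.5)
  p$FC3 <- slerp(p$F3, p$C3, 0.5);  p$FC4 <- slerp(p$F4, p$C4, 0.5)
  p$FT7 <- slerp(p$F7, p$T7, 0.5);  p$FT8 <- slerp(p$F8, p$T8, 0.5)
  p$CP3 <- slerp(p$P3, p$C3, 0.5);  p$CP4 <- slerp(p$P4, p$C4, 0.5)
  p$TP7 <- slerp(p$T7, p$P7, 0.5);  p$TP8 <- slerp(p$T8, p$P8, 0.5)
  order32 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FT7", "FC3", "FCz", "FC4", "FT8", "T7", "C3", "Cz",
               "C4", "T8", "TP7", "CP3", "CPz", "CP4", "TP8", "P7",
               "P3", "Pz", "P4", "P8", "O1", "Oz", "O2", "POz")
  montage(order32, do.call(rbind, p[order32]))
}
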