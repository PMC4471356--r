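# Legendre polynomials P_1..P_nmax evaluated at x (vector) by the
# Bonnet recursion; returns length(x) x nmax matrix
legendre_upto <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))          # P_0
  p <- x                            # P_1
  out[, 1L] <- p
  if (nmax >= 2L) for (nn in 2:nmax) {
    pn <- ((2 * nn - 1) * x * p - (nn - 1) * pm1) / nn
    out[, nn] <- pn
    pm1 <- p; p <- pn
  }
  out
}

#' Spherical-spline kernel
#'
#' The Perrin-style surface spline kernel on the sphere,
#' g(x) = (1/4pi) sum_{n=1}^{max_degree} (2n+1) / (n^m (n+1)^m) P_n(x),
#' where x is the cosine of the angular distance between electrodes,
#' m the stiffness exponent and P_n the Legendre polynomials.
#'
#' @param cos_angle cosine(s) of the angular distance, in [-1, 1]
#'   (values within 1e-12 outside are clamped; larger excursions are
#'   an error).
#' @param m stiffness exponent (default 4).
#' @param max_degree Legendre series truncation (default 7).
#' @return kernel value(s).
#' @export
spline_kernel <- function(cos_angle, m = 4, max_degree = 7) {
  if (any(abs(cos_angle) > 1 + 1e-12))
    stop("cos_angle outside [-1, 1]")
  x <- pmin(1, pmax(-1, cos_angle))
  nn <- seq_len(max_degree)
  coef <- (2 * nn + 1) / (nn^m * (nn + 1)^m)
  P <- legendre_upto(x, max_degree)
  as.vector(P %*% coef) / (4 * pi)
}

#' Spherical-spline interpolation model
#'
#' @param source_positions numeric S x 3 matrix of source electrode
#'   positions (projected to the unit sphere internally).
#' @param target_positions numeric T x 3 matrix of target positions.
#' @param m stiffness exponent (default 4).
#' @param max_degree Legendre truncation (default 7).
#' @param regularization diagonal loading added to the source kernel
#'   matrix, relative to the kernel's diagonal scale (default 1e-6);
#'   stabilizes near-coincident electrodes while keeping exact-node
#'   reproduction errors below 1e-3.
#' @return a `spline_model` list.
#' @export
spline_model <- function(source_positions, target_positions,
                         m = 4, max_degree = 7, regularization = 1e-6) {
  norm_rows <- function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("positions must be n x 3")
    nrm <- sqrt(rowSums(p^2))
    if (any(nrm == 0) || !all(is.finite(p)))
      stop("positions must be finite and nonzero")
    p / nrm
  }
  structure(list(source_positions = norm_rows(source_positions),
                 target_positions = norm_rows(target_positions),
                 m = m, max_degree = max_degree,
                 regularization = regularization),
            class = "spline_model")
}

#' Build the spherical-spline interpolation matrix
#'
#' Solves the spline system with a constant term and diagonal
#' loading:
#' `[G + lambda I, 1; 1', 0] [c; d] = [v; 0]`, then evaluates the
#' spline at the targets.  The returned matrix `M` (targets x
#' sources) maps source signals to target estimates, `M %*% v`.
#' Constant fields are reproduced exactly (the rows sum to 1).
#'
#' @param model a [spline_model()] with at least 3 sources.
#' @return targets x sources weight matrix.
#' @export
build_interpolation_matrix <- function(model) {
  stopifnot(inherits(model, "spline_model"))
  S <- nrow(model$source_positions)
  if (S < 3L) stop("at least 3 source channels are required")
  G <- spline_kernel(tcrossprod(model$source_positions),
                     model$m, model$max_degree)
  G <- matrix(G, S, S)
  # loading is relative to the kernel's diagonal scale, so the
  # regularization strength is invariant to the kernel normalization
  lam <- model$regularization * mean(diag(G))
  C <- rbind(cbind(G + diag(lam, S), rep(1, S)),
             c(rep(1, S), 0))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("rank-deficient electrode positions (coincident sources?)"))
  gt <- spline_kernel(tcrossprod(model$target_positions,
                                 model$source_positions),
                      model$m, model$max_degree)
  gt <- matrix(gt, nrow(model$target_positions), S)
  A <- cbind(gt, rep(1, nrow(gt)))
  (A %*% Ci)[, seq_len(S), drop = FALSE]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces each bad channel with its spherical-spline estimate from
#' all good evaluation channels.  Good channels are untouched
#' bit-wise; the original signals of the interpolated channels are
#' retained in the `"original_bad"` attribute of the result.
#'
#' @param rec an [recording()].
#' @param bad character vector of bad channel labels (possibly
#'   empty).
#' @param m,max_degree,regularization spline parameters, see
#'   [spline_model()].
#' @return the recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, m = 4, max_degree = 7,
                                 regularization = 1e-6) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- intersect(as.character(bad), rec$montage$labels)
  if (length(bad) == 0L) return(rec)
  good <- setdiff(rec$evaluation_channels, bad)
  if (length(good) < 3L)
    stop("fewer than 3 good channels remain; cannot interpolate")
  mont <- normalize_montage(rec$montage)
  model <- spline_model(mont$positions[good, , drop = FALSE],
                        mont$positions[bad, , drop = FALSE],
                        m, max_degree, regularization)
  M <- build_interpolation_matrix(model)
  out <- rec
  orig <- rec$data[bad, , drop = FALSE]
  out$data[bad, ] <- M %*% rec$data[good, , drop = FALSE]
  attr(out, "original_bad") <- orig
  out
}
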