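# Separable Gaussian and derivative operators as banded matrices, so a
# 2-D convolution is two matrix products (row-normalized Gaussian handles
# boundaries; derivative stencils use edge replication).

gauss_matrix <- function(n, sigma) {
  i <- seq_len(n)
  K <- exp(-outer(i, i, function(a, b) (a - b)^2) / (2 * sigma^2))
  K / rowSums(K)
}

deriv2_matrix <- function(n) {
  D <- matrix(0, n, n)
  for (i in 2:(n - 1)) { D[i, i - 1] <- 1; D[i, i] <- -2; D[i, i + 1] <- 1 }
  D[1, ] <- D[2, ]; D[n, ] <- D[n - 1, ]
  D
}

deriv1_matrix <- function(n) {
  D <- matrix(0, n, n)
  for (i in 2:(n - 1)) { D[i, i - 1] <- -0.5; D[i, i + 1] <- 0.5 }
  D[1, ] <- D[2, ]; D[n, ] <- D[n - 1, ]
  D
}

gauss_blur2d <- function(img, sigma) {
  gauss_matrix(nrow(img), sigma) %*% img %*% t(gauss_matrix(ncol(img), sigma))
}

# Scale-normalized negated Laplacian-of-Gaussian response at blob scale
# `scale` (sigma = sqrt(scale / 2)). For a Gaussian spot of amplitude A
# whose size matches the scale, the centre response is A / 2.
log_response2d <- function(img, scale) {
  sigma <- sqrt(scale / 2)
  B <- gauss_blur2d(img, sigma)
  L <- deriv2_matrix(nrow(img)) %*% B + B %*% t(deriv2_matrix(ncol(img)))
  -sigma^2 * L
}

# Scale-normalized bright-ridge (vesselness) response at sigma = scale:
# sigma^2 |lambda2| damped by the Hessian eigenvalue ratio, so an
# isotropic blob of equal amplitude scores exp(-2) of an ideal ridge.
vesselness_response2d <- function(img, scale, beta = 0.5) {
  sigma <- scale
  B <- gauss_blur2d(img, sigma)
  ny <- nrow(img); nx <- ncol(img)
  Hyy <- deriv2_matrix(ny) %*% B
  Hxx <- B %*% t(deriv2_matrix(nx))
  Hxy <- deriv1_matrix(ny) %*% B %*% t(deriv1_matrix(nx))
  tr2 <- (Hxx + Hyy) / 2
  rad <- sqrt(((Hxx - Hyy) / 2)^2 + Hxy^2)
  l1 <- tr2 + rad; l2 <- tr2 - rad
  # order by magnitude: la small, lb large
  swap <- abs(l1) > abs(l2)
  la <- ifelse(swap, l2, l1)
  lb <- ifelse(swap, l1, l2)
  resp <- sigma^2 * abs(lb) * exp(-(la / lb)^2 / (2 * beta^2))
  resp[lb >= 0 | rad == 0] <- 0
  matrix(resp, ny, nx)
}

check_pairs <- function(pairs) {
  if (length(pairs) == 0) stop("at least one (scale, cutoff) pair is required")
  for (p in pairs) {
    if (length(p) != 2) stop("each pair must be (scale, cutoff)")
    if (p[[1]] <= 0) stop("scales must be positive")
    if (p[[2]] < 0) stop("cutoffs must be non-negative")
  }
  invisible(TRUE)
}

#' Multi-scale spot detection, slice by slice
#'
#' For every z slice and every `(scale, cutoff)` pair, computes the
#' scale-normalized negated Laplacian-of-Gaussian response at
#' `sigma = sqrt(scale / 2)` (blob-detector convention: a Gaussian spot of
#' amplitude A at the matched scale responds A/2 at its centre) and keeps
#' pixels whose response exceeds the cutoff. The returned mask is the
#' union over pairs and slices.
#'
#' @param x normalized 2-D `(y, x)` or 3-D `(z, y, x)` array in `[0, 1]`.
#' @param pairs list of `c(scale, cutoff)` pairs, e.g.
#'   `list(c(4, 0.5), c(2, 0.08))`.
#' @return Logical array of the same shape.
#' @export
detect_dots_2d <- function(x, pairs) {
  check_pairs(pairs)
  d <- dim(x)
  if (length(d) == 3L) {
    out <- array(FALSE, d)
    for (z in seq_len(d[1])) out[z, , ] <- detect_dots_2d(x[z, , ], pairs)
    return(out)
  }
  stopifnot(length(d) == 2L)
  mask <- matrix(FALSE, d[1], d[2])
  for (p in pairs)
    mask <- mask | (log_response2d(x, p[[1]]) > p[[2]])
  mask
}

#' Multi-scale filament detection, slice by slice
#'
#' Bright-ridge Hessian (vesselness) response at `sigma = scale` per
#' `(scale, cutoff)` pair, thresholded and unioned over pairs and slices.
#' The response is scale-normalized and damped by the eigenvalue-ratio
#' blobness term, so elongated structures score above isotropic blobs of
#' equal amplitude.
#'
#' @inheritParams detect_dots_2d
#' @return Logical array of the same shape.
#' @export
detect_filaments_2d <- function(x, pairs) {
  check_pairs(pairs)
  d <- dim(x)
  if (length(d) == 3L) {
    out <- array(FALSE, d)
    for (z in seq_len(d[1])) out[z, , ] <- detect_filaments_2d(x[z, , ], pairs)
    return(out)
  }
  stopifnot(length(d) == 2L)
  mask <- matrix(FALSE, d[1], d[2])
  for (p in pairs)
    mask <- mask | (vesselness_response2d(x, p[[1]]) > p[[2]])
  mask
}
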