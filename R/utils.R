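# Internal numeric helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used for the integer location percentages in the grading table
#' (e.g. 37.5 -> 38, 12.5 -> 13).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic sub-seed derivation so that independent noise sources
# (structural speckle, angiographic speckle, motion-channel salt noise) can
# be re-seeded separately from one user-facing seed. Kept below 2^31 - 1.
subseed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483647) * 48271 + 1013 * k) %% 2147483647
}

# Separable Gaussian blur of a depth x lateral matrix via banded kernel
# matrices; kernel rows are renormalised at the edges (no intensity loss).
gauss_kernel_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0.05) return(NULL)
  half <- max(1L, ceiling(3 * sigma_px))
  offs <- -half:half
  w <- exp(-0.5 * (offs / sigma_px)^2)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    idx <- seq_len(n) + offs[j]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + w[j]
  }
  K / rowSums(K)
}

blur_scan <- function(img, sigma_ax_px, sigma_lat_px) {
  Kz <- gauss_kernel_matrix(nrow(img), sigma_ax_px)
  Kx <- gauss_kernel_matrix(ncol(img), sigma_lat_px)
  if (!is.null(Kz)) img <- Kz %*% img
  if (!is.null(Kx)) img <- img %*% t(Kx)
  img
}

# Boxcar local mean of a matrix (window = 2*half+1, edge-renormalised),
# implemented with running sums along each axis.
box_kernel_matrix <- function(n, half) {
  K <- matrix(0, n, n)
  for (j in -half:half) {
    idx <- seq_len(n) + j
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- 1
  }
  K / rowSums(K)
}

box_mean <- function(img, half) {
  Kz <- box_kernel_matrix(nrow(img), half)
  Kx <- box_kernel_matrix(ncol(img), half)
  Kz %*% img %*% t(Kx)
}

# Bilinear sampling of matrix M at fractional (row, col) positions.
# Out-of-range positions return NA.
bilinear <- function(M, ri, ci) {
  nr <- nrow(M); nc <- ncol(M)
  out <- rep(NA_real_, length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  r0 <- pmin(floor(ri[ok]), nr - 1L)
  c0 <- pmin(floor(ci[ok]), nc - 1L)
  fr <- ri[ok] - r0
  fc <- ci[ok] - c0
  v00 <- M[cbind(r0, c0)]
  v10 <- M[cbind(r0 + 1L, c0)]
  v01 <- M[cbind(r0, c0 + 1L)]
  v11 <- M[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
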